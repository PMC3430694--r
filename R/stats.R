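#' Within-subject 2x2 repeated-measures ANOVA (CUE x TASK)
#'
#' Fits the standard within-subject sums-of-squares decomposition with
#' subject-by-effect error strata via `stats::aov`, yielding F(1, n-1) for the
#' CUE and TASK main effects and their interaction.  In a 2x2 within design
#' every effect has a single degree of freedom, so each F equals the squared
#' paired t on the corresponding within-subject contrast and no sphericity
#' correction applies.  A degenerate effect whose contrast is identically
#' zero across subjects (zero effect and zero error sum of squares) is
#' reported as F = 0, p = 1 rather than 0/0.
#'
#' @param data Numeric matrix or data frame, subjects x 4, with columns named
#'   CG, CC, EG, EC (cell means per subject; % errors, ms, or voxel counts).
#' @return Data frame with one row per effect (`CUE`, `TASK`, `CUE:TASK`):
#'   `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(data) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) colnames(data) <- CONDITIONS
  if (!all(CONDITIONS %in% colnames(data))) {
    stop("data must have columns CG, CC, EG, EC")
  }
  data <- data[, CONDITIONS, drop = FALSE]
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 subjects")
  if (any(!is.finite(data))) stop("missing design cells")
  long <- data.frame(
    y = as.vector(data),
    subject = factor(rep(seq_len(n), times = 4L)),
    cue = factor(rep(c("contextual", "contextual", "episodic", "episodic"),
                     each = n)),
    task = factor(rep(c("grammar", "count", "grammar", "count"), each = n))
  )
  fit <- aov(y ~ cue * task + Error(subject / (cue * task)), data = long)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    i <- match(term, trimws(rownames(tab)))
    list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
         ess = tab[nrow(tab), "Sum Sq"], edf = tab[nrow(tab), "Df"])
  }
  effects <- list(CUE = pull("Error: subject:cue", "cue"),
                  TASK = pull("Error: subject:task", "task"),
                  `CUE:TASK` = pull("Error: subject:cue:task", "cue:task"))
  out <- do.call(rbind, lapply(names(effects), function(nm) {
    e <- effects[[nm]]
    scale <- max(abs(data))^2 * n
    if (e$ss <= 1e-12 * max(scale, 1)) {
      F <- 0; p <- 1
    } else {
      F <- (e$ss / e$df) / (e$ess / e$edf)
      p <- stats::pf(F, e$df, e$edf, lower.tail = FALSE)
    }
    data.frame(effect = nm, F = F, df1 = e$df, df2 = e$edf, p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired t test with explicit degenerate-case handling
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = x - y`,
#' `df = n - 1`, two-tailed p.  Zero-variance differences are flagged rather
#' than silently NaN: all-zero differences give t = 0, p = 1; constant
#' nonzero differences give an infinite t (reported as `Inf` with flag) and
#' p = 0.
#'
#' @param x,y Paired numeric vectors (same subjects, same length >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`, `flag` (NA or
#'   `"zero-variance"`).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  flag = "zero-variance"))
    }
    return(list(t = sign(md) * Inf, df = n - 1L, p = 0, mean_diff = md,
                flag = "zero-variance"))
  }
  t <- md / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1L), mean_diff = md,
       flag = NA_character_)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  cor(x, y)
}
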