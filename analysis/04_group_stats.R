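#!/usr/bin/env Rscript
# Stage 4: group statistics.  2x2 repeated-measures ANOVAs (CUE x TASK) on
# error rates, reaction times, and tuned-voxel counts; tuning-success paired
# t tests (each condition's tuned voxels: preferred-condition beta vs the
# mean of the other three); speed-accuracy Pearson correlations per task.

library(voxtune)

beh_files <- sort(list.files("results/behavior", full.names = TRUE))
counts <- read.table("results/tuning_counts.tsv", header = TRUE, sep = "\t")
curves <- read.table("results/tuning_curves.tsv", header = TRUE, sep = "\t")
stopifnot(length(beh_files) > 0L)

subjects <- seq_along(beh_files)
cells <- function(values, cond) {
  vapply(conditions(), function(cc) mean(values[cond == cc]), numeric(1L))
}
err <- t(vapply(beh_files, function(f) {
  b <- read.table(f, header = TRUE, sep = "\t")
  100 * cells(!b$correct, b$condition)
}, numeric(4L)))
rt <- t(vapply(beh_files, function(f) {
  b <- read.table(f, header = TRUE, sep = "\t")
  vapply(conditions(), function(cc) {
    mean(b$rt_ms[b$condition == cc & b$correct])
  }, numeric(1L))
}, numeric(4L)))
rownames(err) <- rownames(rt) <- NULL

cnt <- with(counts, tapply(mean_count, list(subject, condition), mean))
cnt <- cnt[, conditions()]

cat("== behavioral error rates (%) ==\n")
print(round(colMeans(err), 2))
print(rm_anova_2x2(err))
cat("\n== reaction times (ms) ==\n")
print(round(colMeans(rt), 1))
print(rm_anova_2x2(rt))
cat("\n== tuned-voxel counts ==\n")
print(round(colMeans(cnt), 2))
print(rm_anova_2x2(cnt))

cat("\n== tuning success (target vs mean of other conditions) ==\n")
summaries <- lapply(sort(unique(curves$subject)), function(s) {
  cm <- curves[curves$subject == s, ]
  mat <- matrix(NA_real_, 4L, 4L, dimnames = list(conditions(), conditions()))
  mat[cbind(match(cm$preferred, conditions()),
            match(cm$condition, conditions()))] <- cm$mean_beta
  structure(list(curves = mat), class = "tuning_summary")
})
success <- lapply(conditions(), function(cc) {
  r <- suppressWarnings(tuning_success(summaries, cc))
  cat(sprintf("  %s: t(%d) = %.2f, p = %.2g\n", cc, r$df, r$t, r$p))
  r
})
names(success) <- conditions()

cat("\n== speed-accuracy correlations ==\n")
r_grammar <- pearson_r(rowMeans(rt[, c("CG", "EG")]),
                       rowMeans(err[, c("CG", "EG")]))
r_count <- pearson_r(rowMeans(rt[, c("CC", "EC")]),
                     rowMeans(err[, c("CC", "EC")]))
cat(sprintf("  grammar-task: r = %.3f; count-task: r = %.3f\n",
            r_grammar, r_count))

out <- list(
  behavior = list(error_pct = colMeans(err), rt_ms = colMeans(rt),
                  anova_error = rm_anova_2x2(err), anova_rt = rm_anova_2x2(rt)),
  tuning = list(mean_counts = colMeans(cnt),
                anova_counts = rm_anova_2x2(cnt),
                success = lapply(success, function(r) r[c("t", "df", "p")])),
  speed_accuracy = list(grammar = r_grammar, count = r_count)
)
jsonlite::write_json(out, "results/group_stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, force = TRUE)
cat("\nwrote results/group_stats.json\n")
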