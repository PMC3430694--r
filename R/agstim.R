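#' @importFrom stats rnorm runif rbinom qnorm pnorm pt dgamma optimize cor
#'   aov var sd
#' @importFrom utils write.table read.table
NULL

# Syllable alphabet: six plosive consonants crossed with four vowels.  The vowel
# carries the category (A ends in /e/ or /i/, B in /o/ or /u/); voiced/voiceless
# plosives are paired b-p, d-t, g-k to encode the mirrored dependencies.
AG_CONSONANTS <- c("b", "d", "g", "p", "t", "k")
AG_VOWELS <- c("e", "i", "o", "u")
AG_A_VOWELS <- c("e", "i")
AG_B_VOWELS <- c("o", "u")
AG_PLOSIVE_PAIR <- c(b = "p", d = "t", g = "k", p = "b", t = "d", k = "g")

#' Split a syllable string into consonant and vowel
#'
#' A study syllable is a two-character consonant-vowel unit drawn from the six
#' plosives \{b, d, g, p, t, k\} and the four vowels \{e, i, o, u\}.
#'
#' @param s Character scalar, e.g. `"be"`.
#' @return A list with elements `consonant` and `vowel`.
#' @export
syllable_parts <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) != 2L) {
    stop("malformed syllable: expected a two-character consonant-vowel string, got ",
         deparse(s))
  }
  cons <- substr(s, 1L, 1L)
  vow <- substr(s, 2L, 2L)
  if (!(cons %in% AG_CONSONANTS)) {
    stop("malformed syllable '", s, "': consonant must be one of ",
         paste(AG_CONSONANTS, collapse = ", "))
  }
  if (!(vow %in% AG_VOWELS)) {
    stop("malformed syllable '", s, "': vowel must be one of ",
         paste(AG_VOWELS, collapse = ", "))
  }
  list(consonant = cons, vowel = vow)
}

#' Classify a syllable as category A or B
#'
#' Category membership is carried by the vowel: A syllables end in /e/ or /i/,
#' B syllables in /o/ or /u/.
#'
#' @param s Character scalar syllable.
#' @return `"A"` or `"B"`.
#' @examples
#' classify_syllable("be")  # "A"
#' classify_syllable("ko")  # "B"
#' @export
classify_syllable <- function(s) {
  p <- syllable_parts(s)
  if (p$vowel %in% AG_A_VOWELS) "A" else "B"
}

#' Parse a space-separated syllable sequence
#'
#' @param x Either a character vector of syllables or a single space-separated
#'   string such as `"be di ge ko tu pu"`.
#' @return Character vector of validated syllables.
#' @export
parse_sequence <- function(x) {
  if (length(x) == 1L && grepl(" ", x)) {
    x <- strsplit(trimws(x), "\\s+")[[1]]
  }
  x <- as.character(x)
  for (s in x) syllable_parts(s)  # validate each
  x
}

#' Check the center-embedded AnBn grammaticality of a sequence
#'
#' A sequence of length 2n is grammatical when the first n syllables are
#' category A, the last n are category B, and the consonant of the i-th A
#' syllable is the plosive partner (b-p, d-t, g-k) of the consonant at the
#' mirrored position 2n+1-i, i.e. the dependencies are center-embedded
#' A1 A2 ... An Bn ... B2 B1.
#'
#' @param seq Character vector of syllables or a space-separated string.
#' @return Logical scalar.
#' @examples
#' is_grammatical("be di ge ko tu pu")  # TRUE
#' is_grammatical("be di ge ko pu tu")  # FALSE: B consonants permuted
#' @export
is_grammatical <- function(seq) {
  seq <- parse_sequence(seq)
  len <- length(seq)
  if (len == 0L) stop("empty sequence")
  if (len %% 2L != 0L) stop("sequence length must be even, got ", len)
  n <- len %/% 2L
  cats <- vapply(seq, classify_syllable, character(1L))
  if (any(cats[seq_len(n)] != "A") || any(cats[n + seq_len(n)] != "B")) {
    return(FALSE)
  }
  cons <- substr(seq, 1L, 1L)
  for (i in seq_len(n)) {
    if (AG_PLOSIVE_PAIR[[cons[i]]] != cons[2L * n + 1L - i]) return(FALSE)
  }
  TRUE
}

#' Check the count/match property of a sequence
#'
#' The count task asks whether the number of syllables ending in /e/ equals the
#' number ending in /o/.
#'
#' @param seq Character vector of syllables or a space-separated string.
#' @return Logical scalar.
#' @examples
#' count_match("be di ge ko tu pu")  # FALSE: two /e/, one /o/
#' count_match("be do")              # TRUE
#' @export
count_match <- function(seq) {
  seq <- parse_sequence(seq)
  if (length(seq) == 0L) stop("empty sequence")
  vows <- substr(seq, 2L, 2L)
  sum(vows == "e") == sum(vows == "o")
}

# Sample the /e/-count among A positions and /o/-count among B positions so that
# the resulting vowel assignment is uniform over all assignments satisfying the
# requested count_match label.  Only A syllables can end in /e/ and only B
# syllables in /o/, so the counts ke, ko each range over 0..n.
.sample_vowel_counts <- function(n, countmatch) {
  grid <- expand.grid(ke = 0:n, ko = 0:n)
  ok <- if (countmatch) grid$ke == grid$ko else grid$ke != grid$ko
  grid <- grid[ok, , drop = FALSE]
  w <- choose(n, grid$ke) * choose(n, grid$ko)
  pick <- grid[sample.int(nrow(grid), 1L, prob = w), ]
  list(ke = pick$ke, ko = pick$ko)
}

#' Generate one AnBn stimulus sequence with requested labels
#'
#' Grammatical sequences are built constructively: n distinct voiced-plosive A
#' syllables (consonants from \{b, d, g\}) followed by their voiceless partners
#' in mirrored order.  Ungrammatical sequences keep the A-block/B-block shape
#' and differ only by a permutation of the B consonants that leaves at least one
#' mirrored pair mismatched.  Vowels are drawn uniformly among all assignments
#' satisfying the requested count/match label.  Randomness comes from the
#' session RNG; call `set.seed()` for reproducibility.
#'
#' @param n Embedding depth (the study uses n = 3; must be 1..3 so that A
#'   consonants can be distinct).
#' @param grammatical Logical, requested grammaticality label.
#' @param countmatch Logical, requested count/match label.
#' @return A list of class `ag_sequence` with elements `syllables`,
#'   `is_grammatical`, `count_match`, `n`.
#' @export
generate_sequence <- function(n = 3L, grammatical = TRUE, countmatch = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("embedding depth n must be >= 1")
  if (n > 3L) stop("n > 3 unsupported: only three plosive pairs are available ",
                   "for distinct mirrored dependencies")
  if (n == 1L && !grammatical) {
    stop("unsatisfiable label combination: with n = 1 a B-consonant ",
         "permutation cannot break the single mirrored pair")
  }
  a_cons <- sample(c("b", "d", "g"), n)
  b_cons <- rev(unname(AG_PLOSIVE_PAIR[a_cons]))  # mirrored partners
  if (!grammatical) {
    repeat {
      perm <- sample(b_cons)
      if (any(perm != b_cons)) break
    }
    b_cons <- perm
  }
  counts <- .sample_vowel_counts(n, countmatch)
  a_vows <- sample(c(rep("e", counts$ke), rep("i", n - counts$ke)))
  b_vows <- sample(c(rep("o", counts$ko), rep("u", n - counts$ko)))
  syll <- c(paste0(a_cons, a_vows), paste0(b_cons, b_vows))
  out <- list(syllables = syll,
              is_grammatical = grammatical,
              count_match = countmatch,
              n = n)
  class(out) <- "ag_sequence"
  stopifnot(is_grammatical(syll) == grammatical,
            count_match(syll) == countmatch)
  out
}

#' @export
format.ag_sequence <- function(x, ...) paste(x$syllables, collapse = " ")

#' @export
print.ag_sequence <- function(x, ...) {
  cat(format(x), " [grammatical: ", x$is_grammatical,
      ", count-match: ", x$count_match, "]\n", sep = "")
  invisible(x)
}

#' Enumerate all block-shaped sequences at depth n
#'
#' Every sequence whose first n syllables are category A and last n category B,
#' over the full 6-consonant x 2-vowel-per-category alphabet.  Intended for
#' exhaustive cross-checks of the grammaticality checker at small n (12^(2n)
#' sequences; n = 2 gives 20,736).
#'
#' @param n Embedding depth.
#' @return Character matrix with 2n columns, one row per sequence.
#' @export
enumerate_block_sequences <- function(n = 2L) {
  a_syll <- as.vector(outer(AG_CONSONANTS, AG_A_VOWELS, paste0))
  b_syll <- as.vector(outer(AG_CONSONANTS, AG_B_VOWELS, paste0))
  pools <- c(rep(list(a_syll), n), rep(list(b_syll), n))
  grid <- do.call(expand.grid, c(pools, list(stringsAsFactors = FALSE)))
  as.matrix(grid)
}

#' Write a stimulus table to TSV
#'
#' @param sequences List of `ag_sequence` objects.
#' @param path Output TSV path.
#' @param seed Seed recorded alongside each row (metadata only).
#' @return The data frame written, invisibly.
#' @export
write_stimulus_table <- function(sequences, path, seed = NA_integer_) {
  df <- data.frame(
    sequence = vapply(sequences, format, character(1L)),
    n = vapply(sequences, function(s) s$n, integer(1L)),
    is_grammatical = vapply(sequences, function(s) s$is_grammatical, logical(1L)),
    count_match = vapply(sequences, function(s) s$count_match, logical(1L)),
    seed = seed
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
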