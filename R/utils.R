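## internal helpers shared across modules

.zones <- c("oxic", "redoxcline", "euxinic", "unknown")

.exclusivity_classes <- c("cosmopolitan", "cariaco_only", "euxinic_only",
                          "redoxcline_only", "redoxcline_and_euxinic",
                          "undetectable")

.distribution_classes <- c("cosmopolitan", "oxygenated_only", "euxinic_only",
                           "redoxcline_only", "redoxcline_and_euxinic",
                           "indeterminate")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## evaluate `code` under a fixed RNG state, restoring the caller's state
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

.check_zone <- function(zone) {
  bad <- setdiff(unique(zone), .zones)
  if (length(bad))
    .stopf("unknown zone(s): %s (expected %s)",
           paste(bad, collapse = ", "), paste(.zones, collapse = "/"))
  invisible(zone)
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. draws over A/C/G/T. Used by the synthetic-virome generator
#' and handy for constructing test fixtures.
#'
#' @param length Sequence length in bp.
#' @return A character scalar.
#' @export
randomDNA <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence by random substitutions
#'
#' Each position is substituted independently with probability `rate`,
#' always to a different base (no indels), so the expected per-site
#' divergence from the input equals `rate`.
#'
#' @param sequence Character scalar over A/C/G/T/N.
#' @param rate Per-site substitution probability in \[0, 1\].
#' @return The mutated sequence (character scalar).
#' @export
mutateSequence <- function(sequence, rate) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            rate >= 0, rate <= 1)
  if (rate == 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1), USE.NAMES = FALSE)
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}
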