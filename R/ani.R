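## Pairwise ANI between contigs.
##
## Two routes: a seeded-diagonal scan (exact 15-mer anchors, gap-free
## extension over the best diagonal, both strands) suitable for long
## contigs, and a quadratic dynamic-programming global alignment
## (Needleman-Wunsch via Biostrings) for sequences <= 2 kb, which doubles
## as the independent oracle in the test suite. Identity is
## 100 * matches / aligned columns; N never matches anything and gap
## columns count against identity through the denominator.

.dp_max_len <- 2000L

.ani_subst_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      mm <- matrix(-2, 5, 5, dimnames = list(bases, bases))
      diag(mm) <- 1
      mm["N", ] <- -2
      mm[, "N"] <- -2  # N mismatches everything, including N
      m <<- mm
    }
    m
  }
})

.as_seq <- function(x, arg) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet")) {
    if (methods::is(x, "DNAStringSet")) {
      if (length(x) != 1L) .stopf("'%s' must be a single sequence", arg)
      x <- x[[1]]
    }
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L)
    .stopf("'%s' must be a single DNA sequence", arg)
  s <- toupper(x)
  if (!nzchar(s)) .stopf("'%s' is empty", arg)
  if (grepl("[^ACGTN]", s)) .stopf("'%s' contains non-ACGTN characters", arg)
  if (!grepl("[ACGT]", s)) .stopf("unalignable: '%s' contains only N", arg)
  s
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.ani_seed_one <- function(q, t, k) {
  r <- ani_diagonal_cpp(q, t, as.integer(k))
  list(matches = r$matches, columns = r$span)
}

.ani_dp_one <- function(q, t) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(t),
    substitutionMatrix = .ani_subst_matrix(),
    gapOpening = 10, gapExtension = 4, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-" & p != "N")
  list(matches = matches, columns = length(p))
}

#' Pairwise average nucleotide identity between two contigs
#'
#' Computes ANI and the aligned fraction of the shorter sequence, on both
#' strands, returning the better strand. The default `"auto"` method uses
#' the quadratic dynamic-programming global alignment when both sequences
#' are at most 2 kb and the seeded-diagonal scan otherwise; `"seed"` and
#' `"dp"` force a route (`"dp"` refuses sequences over 2 kb).
#'
#' When the seeded route finds no exact-match anchor on either strand
#' (effectively unrelated sequences), ANI is reported as 0 with aligned
#' fraction 0.
#'
#' @param a,b Sequences (character scalars, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @param seedLength Exact-match seed length for the seeded route.
#' @param method `"auto"`, `"seed"` or `"dp"`.
#' @return A one-row `data.frame` with columns `ani_percent`,
#'   `aligned_fraction_shorter`, `strand` (`"plus"`/`"minus"`), `matches`,
#'   `aligned_columns`, `method`. Symmetric under swapping `a` and `b`.
#' @seealso [clusterPopulations()]
#' @export
pairwiseANI <- function(a, b, seedLength = 15L,
                        method = c("auto", "seed", "dp")) {
  method <- match.arg(method)
  qa <- .as_seq(a, "a")
  tb <- .as_seq(b, "b")
  if (method == "auto")
    method <- if (nchar(qa) <= .dp_max_len && nchar(tb) <= .dp_max_len)
      "dp" else "seed"
  if (method == "dp" && (nchar(qa) > .dp_max_len || nchar(tb) > .dp_max_len))
    .stopf("dp method is restricted to sequences <= %d bp", .dp_max_len)
  one <- if (method == "dp") .ani_dp_one else
    function(q, t) .ani_seed_one(q, t, seedLength)
  fwd <- one(qa, tb)
  rev <- one(qa, .revcomp(tb))
  pick <- if (rev$matches > fwd$matches) "minus" else "plus"
  hit <- if (pick == "minus") rev else fwd
  shorter <- min(nchar(qa), nchar(tb))
  if (hit$columns == 0L) {
    return(data.frame(ani_percent = 0, aligned_fraction_shorter = 0,
                      strand = "plus", matches = 0L, aligned_columns = 0L,
                      method = method, stringsAsFactors = FALSE))
  }
  data.frame(
    ani_percent = 100 * hit$matches / hit$columns,
    aligned_fraction_shorter = min(1, hit$columns / shorter),
    strand = pick,
    matches = hit$matches,
    aligned_columns = hit$columns,
    method = method,
    stringsAsFactors = FALSE)
}
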