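# Internal helpers shared across modules.

# IUPAC nucleotide codes -> character classes (N deliberately maps to ACGT so
# that an N in a *sequence* can never satisfy a motif position).
IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' @noRd
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    bad <- !(ch %in% names(COMPLEMENT))
    if (any(bad)) stop("cannot reverse-complement symbol(s): ",
                       paste(unique(ch[bad]), collapse = ","))
    paste(COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' @noRd
iupac_to_regex <- function(iupac) {
  ch <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(IUPAC_MAP))
  if (any(bad)) stop("invalid IUPAC symbol(s): ", paste(unique(ch[bad]), collapse = ","))
  paste(vapply(ch, function(c0) {
    cls <- IUPAC_MAP[[c0]]
    if (nchar(cls) == 1L) cls else paste0("[", cls, "]")
  }, character(1)), collapse = "")
}

# All (overlapping) 1-based start positions of an IUPAC motif on a string.
#' @noRd
iupac_match_starts <- function(seq, iupac) {
  re <- paste0("(?=", iupac_to_regex(iupac), ")")
  m <- gregexpr(re, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}
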