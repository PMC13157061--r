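# Independent oracles for global affine-gap alignment, used only in tests.
# Gap of length L costs open + L * ext; end gaps are penalized.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Pure enumeration over all alignments (no DP): exponential, tiny inputs only.
enumerate_align_score <- function(a, b, submat = blosum62,
                                  open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) {
      return(0)
    }
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(ca)) { # gap in b
      pen <- ext + if (prev == "D") 0 else open
      best <- max(best, rec(i + 1, j, "D") - pen)
    }
    if (j <= length(cb)) { # gap in a
      pen <- ext + if (prev == "I") 0 else open
      best <- max(best, rec(i, j + 1, "I") - pen)
    }
    best
  }
  rec(1, 1, "start")
}

# Independent Gotoh three-state DP in plain R (cross-checked against the
# enumerator on tiny cases, then usable on longer test sequences).
gotoh_align_score <- function(a, b, submat = blosum62, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  neg <- -Inf
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(neg, n + 1, m + 1) # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[ca[i - 1], cb[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_protein <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
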