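protein_alphabet <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "K", "L", "M", "F", "P", "S", "T", "W", "Y", "V", "X"
)

load_substitution_matrix <- function(name) {
  known <- c(
    "BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
    "PAM30", "PAM40", "PAM70", "PAM120", "PAM250"
  )
  if (!name %in% known) {
    stop(
      "unknown substitution matrix '", name, "'; available: ",
      paste(known, collapse = ", "),
      call. = FALSE
    )
  }
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

as_protein_string <- function(x, arg = "sequence") {
  if (inherits(x, "AAStringSet")) {
    if (length(x) != 1L) stop("expected a single ", arg, call. = FALSE)
    x <- x[[1]]
  }
  x <- toupper(as.character(x))
  if (length(x) != 1L || !nzchar(x)) {
    stop(arg, " must be a single non-empty protein sequence", call. = FALSE)
  }
  residues <- strsplit(x, "")[[1]]
  bad <- setdiff(unique(residues), protein_alphabet)
  if (length(bad)) {
    stop(arg, " contains invalid residue(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  x
}

#' Read protein sequences from FASTA
#'
#' Thin validated wrapper over [Biostrings::readAAStringSet()]: sequences
#' must be non-empty and restricted to the 20 amino-acid letters plus `X`.
#'
#' @param path Path to a protein FASTA file.
#' @return An `AAStringSet`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  for (i in seq_along(seqs)) {
    as_protein_string(as.character(seqs[[i]]), arg = names(seqs)[i])
  }
  seqs
}

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties and
#' end gaps penalized, scored with a standard substitution matrix
#' (default BLOSUM62, gap opening 10, gap extension 0.5 per gap position).
#' The dynamic programming is done by [Biostrings::pairwiseAlignment()];
#' this function adds validation, the identity/similarity summary, and a
#' stable result container.
#'
#' @param a,b Protein sequences (character, `AAString`, or single-sequence
#'   `AAStringSet`).
#' @param matrix Substitution matrix label (e.g. `"BLOSUM62"`).
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty per gap position (positive).
#' @param id_a,id_b Optional sequence labels for reports.
#' @return An object of class `alignment_result`: gapped strings
#'   `aligned_a`/`aligned_b`, `score`, `identity_pct`, `similarity_pct`,
#'   `length` (alignment columns), and the scoring settings.
#' @examples
#' r <- global_align("HEAGAWGHEE", "PAWHEAE")
#' r$score
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, id_a = "a", id_b = "b") {
  sa <- as_protein_string(a, "a")
  sb <- as_protein_string(b, "b")
  submat <- load_substitution_matrix(matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  aligned_a <- as.character(Biostrings::alignedPattern(al))
  aligned_b <- as.character(Biostrings::alignedSubject(al))
  res <- structure(
    list(
      id_a = id_a, id_b = id_b,
      aligned_a = unname(aligned_a), aligned_b = unname(aligned_b),
      score = Biostrings::score(al),
      matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
      length = nchar(aligned_a)
    ),
    class = "alignment_result"
  )
  pcts <- identity_similarity(res)
  res$identity_pct <- pcts[["identity_pct"]]
  res$similarity_pct <- pcts[["similarity_pct"]]
  res
}

#' Percent identity and similarity of an alignment
#'
#' Identity is the fraction of alignment columns with identical residues;
#' similarity ("conservation") is the fraction of columns whose residue
#' pair has a positive substitution-matrix score — identities plus
#' conservative substitutions. Both use the full alignment length
#' (including gap columns) as denominator, so
#' `0 <= identity <= similarity <= 100`.
#'
#' @param r An `alignment_result` from [global_align()].
#' @return Named numeric vector `c(identity_pct, similarity_pct)`.
#' @export
identity_similarity <- function(r) {
  stopifnot(inherits(r, "alignment_result"))
  ca <- strsplit(r$aligned_a, "")[[1]]
  cb <- strsplit(r$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  submat <- load_substitution_matrix(r$matrix)
  both <- ca != "-" & cb != "-"
  identical_cols <- sum(ca[both] == cb[both])
  positive_cols <- sum(submat[cbind(
    match(ca[both], rownames(submat)),
    match(cb[both], colnames(submat))
  )] > 0)
  n <- length(ca)
  c(
    identity_pct = 100 * identical_cols / n,
    similarity_pct = 100 * positive_cols / n
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$id_a, " vs ", x$id_b, "\n", sep = "")
  cat(sprintf(
    "  %s, gap open %g / extend %g; length %d, score %.1f\n",
    x$matrix, x$gap_open, x$gap_extend, x$length, x$score
  ))
  cat(sprintf(
    "  identity %.1f%%, similarity %.1f%%\n",
    x$identity_pct, x$similarity_pct
  ))
  invisible(x)
}

#' Plain-text pairwise alignment report
#'
#' Formats an alignment block-wise (60 columns per block) with a match
#' line (`|` identity, `:` positive substitution score) and the summary
#' percentages, in the style of standard pairwise alignment reports.
#'
#' @param r An `alignment_result`.
#' @param width Columns per block.
#' @return Character vector of report lines.
#' @export
alignment_report <- function(r, width = 60) {
  stopifnot(inherits(r, "alignment_result"))
  submat <- load_substitution_matrix(r$matrix)
  ca <- strsplit(r$aligned_a, "")[[1]]
  cb <- strsplit(r$aligned_b, "")[[1]]
  marks <- vapply(seq_along(ca), function(i) {
    if (ca[i] == "-" || cb[i] == "-") {
      " "
    } else if (ca[i] == cb[i]) {
      "|"
    } else if (submat[ca[i], cb[i]] > 0) {
      ":"
    } else {
      "."
    }
  }, character(1))
  header <- c(
    sprintf("# %s vs %s", r$id_a, r$id_b),
    sprintf("# matrix %s, gap open %g, gap extend %g", r$matrix, r$gap_open, r$gap_extend),
    sprintf("# length %d, score %.1f", r$length, r$score),
    sprintf("# identity %.1f%%, similarity %.1f%%", r$identity_pct, r$similarity_pct),
    ""
  )
  blocks <- lapply(seq(1, r$length, by = width), function(start) {
    idx <- start:min(start + width - 1, r$length)
    c(
      paste0(format(r$id_a, width = 10), " ", paste(ca[idx], collapse = "")),
      paste0(strrep(" ", 11), paste(marks[idx], collapse = "")),
      paste0(format(r$id_b, width = 10), " ", paste(cb[idx], collapse = "")),
      ""
    )
  })
  c(header, unlist(blocks))
}

#' Bundled Galpha-o ortholog sequences (synthetic reconstructions)
#'
#' Returns the two bundled protein sequences used by the conservation
#' workflow: C. elegans GOA-1 and human GNAO1. These FASTA files are
#' best-effort synthetic reconstructions of the canonical proteins written
#' from domain knowledge, not database records, and carry "synthetic" in
#' their filenames; alignments computed from them approximate but do not
#' reproduce database-derived identity/similarity percentages. Substitute
#' curated FASTA files (e.g. UniProt P51875 and P09471) for real analyses.
#'
#' @return Named list with elements `goa1` and `gnao1` (`AAStringSet`s).
#' @export
goa1_gnao1_sequences <- function() {
  list(
    goa1 = read_protein_fasta(
      system.file("extdata", "goa1_celegans_synthetic.fasta",
        package = "wormpharm", mustWork = TRUE
      )
    ),
    gnao1 = read_protein_fasta(
      system.file("extdata", "gnao1_human_synthetic.fasta",
        package = "wormpharm", mustWork = TRUE
      )
    )
  )
}
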