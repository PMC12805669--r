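#' Nucleotide alignment with compressed site patterns
#'
#' An `alignment` stores a multiple sequence alignment column-wise as unique
#' site patterns with multiplicities, the form consumed by the pruning
#' likelihood. Symbols outside `A,C,G,T` (gaps, `?`, `N`, IUPAC ambiguities)
#' are kept verbatim and treated as fully missing data downstream.
#'
#' @param sequences named character vector of aligned sequences (equal
#'   length, unique names).
#' @return An object of class `alignment` with fields `taxa`, `patterns`
#'   (character matrix, taxa x patterns), `pattern_weights` (integer counts),
#'   and `site_count`.
#' @examples
#' aln <- alignment(c(t1 = "ACGT", t2 = "ACGA"))
#' aln$site_count
#' @export
alignment <- function(sequences) {
  if (length(sequences) == 0L) stop("alignment: no sequences")
  taxa <- names(sequences)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == "")) {
    stop("alignment: sequences must be named")
  }
  if (anyDuplicated(taxa)) stop("alignment: duplicate taxon label")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("alignment: sequences have unequal lengths")
  }
  n_sites <- lens[[1]]
  if (n_sites == 0L) stop("alignment: zero-length sequences")
  chars <- toupper(do.call(rbind, strsplit(unname(sequences), "", fixed = TRUE)))
  rownames(chars) <- taxa
  # compress identical columns
  keys <- apply(chars, 2, paste, collapse = "")
  tab <- table(factor(keys, levels = unique(keys)))
  patterns <- chars[, match(names(tab), keys), drop = FALSE]
  structure(list(
    taxa = taxa,
    patterns = patterns,
    pattern_weights = as.integer(tab),
    site_count = as.integer(n_sites)
  ), class = "alignment")
}

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file of aligned nucleotide sequences.
#' @return An [alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_fasta: empty file")
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("read_fasta: file does not start with a FASTA header")
  idx <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(labels)) stop("read_fasta: header without sequence")
  seqs <- gsub("\\s", "", seqs)
  names(seqs) <- labels
  alignment(seqs)
}

#' Write an alignment (or named sequences) as FASTA
#'
#' @param x an [alignment] or a named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "alignment")) x <- expand_alignment(x)
  out <- character(2L * length(x))
  out[c(TRUE, FALSE)] <- paste0(">", names(x))
  out[c(FALSE, TRUE)] <- unname(x)
  writeLines(out, path)
  invisible(path)
}

#' Expand compressed patterns back to full sequences
#'
#' Inverse of the pattern compression up to site order: sites are emitted
#' pattern-by-pattern, so likelihoods (which are order-invariant) are
#' preserved exactly.
#'
#' @param aln an [alignment].
#' @return named character vector of sequences.
#' @export
expand_alignment <- function(aln) {
  cols <- rep.int(seq_along(aln$pattern_weights), aln$pattern_weights)
  full <- aln$patterns[, cols, drop = FALSE]
  stats::setNames(apply(full, 1, paste, collapse = ""), aln$taxa)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d taxa, %d sites, %d unique patterns\n",
              length(x$taxa), x$site_count, length(x$pattern_weights)))
  invisible(x)
}

# Tip partial-likelihood vectors for one symbol: indicator for A,C,G,T,
# all-ones for anything else (missing/ambiguous treated as fully missing).
state_partial <- function(symbol) {
  i <- match(symbol, c("A", "C", "G", "T"))
  if (is.na(i)) rep(1, 4) else { v <- numeric(4); v[i] <- 1; v }
}

# 4 x n_patterns tip partial matrix for one taxon
tip_partials <- function(aln, taxon) {
  row <- aln$patterns[match(taxon, aln$taxa), ]
  vapply(row, state_partial, numeric(4))
}
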