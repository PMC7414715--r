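# Family alignment input/output and paralog-pair extraction.
#
# A family alignment holds the aligned amino-acid sequences of all genes of
# one family, one row per gene.  The residue alphabet after normalization is
# the 20 standard amino acids, '-' for gaps and 'X' for any ambiguous or
# unknown residue.

#' Construct a family alignment
#'
#' Builds a validated family alignment from aligned sequences.  Sequences are
#' uppercased and normalized: `.` becomes the gap character `-`, and the
#' ambiguity/rare codes `B`, `Z`, `J`, `U`, `O`, `*` and `?` become `X`.
#'
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param gene_ids Character vector of unique gene identifiers.
#' @return An object of class `family_alignment`: a list with `mat` (character
#'   matrix, genes x columns, rownames are gene ids), `gene_ids` and `length`
#'   (number of alignment columns).
#' @export
family_alignment <- function(seqs, gene_ids = names(seqs)) {
  if (length(seqs) < 1L)
    rf_stop("refates_format_error", "alignment must contain at least one sequence")
  if (is.null(gene_ids) || any(is.na(gene_ids)) || any(gene_ids == ""))
    rf_stop("refates_identity_error", "every sequence needs a gene id")
  if (anyDuplicated(gene_ids))
    rf_stop("refates_identity_error", "duplicate gene ids: %s",
            paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (any(lens == 0L))
    rf_stop("refates_format_error", "empty sequence for gene %s",
            gene_ids[which(lens == 0L)[1L]])
  if (length(unique(lens)) != 1L)
    rf_stop("refates_shape_error",
            "sequences have unequal lengths (%s)",
            paste(unique(lens), collapse = ", "))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  seqs <- chartr("BZJUO", "XXXXX", seqs)
  seqs <- gsub("[*?]", "X", seqs)
  bad <- grepl(sprintf("[^-X%s]", paste(AA_ORDER, collapse = "")), seqs)
  if (any(bad))
    rf_stop("refates_format_error", "invalid residue characters in gene %s",
            gene_ids[which(bad)[1L]])
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(gene_ids, NULL))
  structure(list(mat = mat, gene_ids = gene_ids, length = ncol(mat)),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("family alignment: %d genes x %d columns\n",
              length(x$gene_ids), x$length))
  invisible(x)
}

#' Read a family alignment from a FASTA file
#'
#' @param path Path to an aligned FASTA file (gaps as `-`).
#' @return A [family_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    rf_stop("refates_format_error", "alignment file not found: %s", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     rf_stop("refates_format_error",
                             "could not parse FASTA %s: %s", path,
                             conditionMessage(e)))
  if (length(seqs) == 0L)
    rf_stop("refates_format_error", "no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(seqs))
  family_alignment(as.character(seqs), ids)
}

#' Write a family alignment to FASTA
#'
#' @param aln A [family_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "family_alignment"))
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- aln$gene_ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a gene-to-species map
#'
#' Reads a two-column TSV (gene id, species id).  A header row is detected
#' automatically when the first row looks like column names (e.g. `gene`,
#' `gene_id`, `species`).
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping gene id to species id.
#' @export
read_gene_species_map <- function(path) {
  if (!file.exists(path))
    rf_stop("refates_format_error", "gene-species map not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 2L)
    rf_stop("refates_format_error", "map %s needs two tab-separated columns", path)
  tab <- tab[, 1:2]
  hdr <- tolower(trimws(unlist(tab[1L, ])))
  if (any(hdr %in% c("gene", "gene_id", "geneid", "id")) ||
      any(hdr %in% c("species", "species_id", "speciesid")))
    tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L)
    rf_stop("refates_format_error", "map %s has no entries", path)
  genes <- trimws(tab[[1L]]); species <- trimws(tab[[2L]])
  dup <- duplicated(genes)
  if (any(dup)) {
    for (g in unique(genes[dup])) {
      if (length(unique(species[genes == g])) > 1L)
        rf_stop("refates_identity_error",
                "gene %s mapped to multiple species", g)
    }
    keep <- !dup
    genes <- genes[keep]; species <- species[keep]
  }
  stats::setNames(species, genes)
}

#' Extract single paralog pairs
#'
#' Returns one paralog pair per species that has exactly two genes in the
#' family.  Species with one copy, or with three or more copies (additional
#' duplications or losses), contribute no pair and are ignored.
#'
#' @param aln A [family_alignment()].
#' @param gene_map Named character vector from [read_gene_species_map()].
#' @return Data frame with columns `species_id`, `gene_a`, `gene_b` (genes in
#'   lexicographic order), ordered by species id.
#' @export
extract_paralog_pairs <- function(aln, gene_map) {
  stopifnot(inherits(aln, "family_alignment"))
  missing <- setdiff(aln$gene_ids, names(gene_map))
  if (length(missing))
    rf_stop("refates_identity_error",
            "genes missing from the species map: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  sp <- gene_map[aln$gene_ids]
  counts <- table(sp)
  two <- sort(names(counts)[counts == 2L])
  rows <- lapply(two, function(s) {
    g <- sort(aln$gene_ids[sp == s])
    data.frame(species_id = s, gene_a = g[1L], gene_b = g[2L],
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(species_id = character(), gene_a = character(),
                      gene_b = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Remove gap-rich alignment columns
#'
#' Retains columns whose gap fraction is at most `max_gap_frac`.  Used as an
#' optional pre-step for the duplication-score (likelihood) path; fate
#' statistics are computed on the untrimmed alignment so that recurrent
#' patterns outside conserved regions are not lost.
#'
#' @param aln A [family_alignment()].
#' @param max_gap_frac Maximum tolerated gap fraction per column, in `[0, 1]`.
#' @return A list with `alignment` (the trimmed [family_alignment()]) and
#'   `column_map`, an integer vector giving for each retained (new) column its
#'   original 1-based column index.
#' @export
trim_gappy_columns <- function(aln, max_gap_frac = 0.5) {
  stopifnot(inherits(aln, "family_alignment"),
            is.numeric(max_gap_frac), max_gap_frac >= 0, max_gap_frac <= 1)
  gap_frac <- colMeans(aln$mat == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0L)
    rf_stop("refates_degenerate_error",
            "all %d columns exceed gap fraction %.2f", aln$length, max_gap_frac)
  out <- aln
  out$mat <- aln$mat[, keep, drop = FALSE]
  out$length <- length(keep)
  list(alignment = out, column_map = keep)
}

# Integer encoding of an alignment: 1..20 index AA_ORDER, GAP_CODE marks
# gaps, NA marks ambiguous residues ('X').  Gaps and NAs both count as
# missing for pattern counting and likelihoods; the gap code is kept distinct
# because presence/absence is itself informative for column-level pattern
# mapping (e.g. target-peptide blocks).
GAP_CODE <- 21L

encode_alignment <- function(aln) {
  codes <- match(aln$mat, c(AA_ORDER, "-"))
  matrix(codes, nrow = nrow(aln$mat), dimnames = dimnames(aln$mat))
}
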