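# FASTA and exon-table readers/writers shared by all pipeline stages.

#' Read a FASTA file of protein sequences
#'
#' Sequences are upper-cased, validated against the 20-letter alphabet and
#' returned in file order.
#'
#' @param path Path to a FASTA file.
#' @param allow_unknown Permit `X` residues (see [protein_record()]).
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path, allow_unknown = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input: ", path, call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    protein_record(id, as.character(set[[i]]), desc,
                   allow_unknown = allow_unknown)
  })
}

#' Write protein records to FASTA
#'
#' @param records A list of [protein_record()] objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read an exon table
#'
#' The contract format is a headered TSV with integer columns `exon_number`,
#' `protein_start`, `protein_end` (1-based inclusive protein-residue spans).
#' Rows are returned sorted by `exon_number` with a derived `length_aa`
#' column.
#'
#' @param path Path to the TSV file.
#' @param require_contiguous Additionally require that consecutive exon spans
#'   tile with no gap (default `FALSE`: only non-overlap is enforced).
#' @return A `data.frame` with columns `exon_number`, `protein_start`,
#'   `protein_end`, `length_aa`.
#' @export
read_exon_table <- function(path, require_contiguous = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exon_number", "protein_start", "protein_end")
  if (!all(need %in% names(tab)))
    stop("exon table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- tab[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
      stop("exon table column '", col, "' must be integer", call. = FALSE)
    tab[[col]] <- as.integer(v)
  }
  exon_table(tab$exon_number, tab$protein_start, tab$protein_end,
             require_contiguous = require_contiguous)
}

#' Construct and validate an exon table in memory
#'
#' @param exon_number,protein_start,protein_end Integer vectors.
#' @inheritParams read_exon_table
#' @return A validated exon `data.frame` sorted by `exon_number`.
#' @export
exon_table <- function(exon_number, protein_start, protein_end,
                       require_contiguous = FALSE) {
  d <- data.frame(exon_number = as.integer(exon_number),
                  protein_start = as.integer(protein_start),
                  protein_end = as.integer(protein_end),
                  stringsAsFactors = FALSE)
  if (any(duplicated(d$exon_number)))
    stop("duplicated exon_number", call. = FALSE)
  d <- d[order(d$exon_number), , drop = FALSE]
  rownames(d) <- NULL
  if (any(d$protein_start > d$protein_end))
    stop("exon with protein_start > protein_end", call. = FALSE)
  if (nrow(d) > 1L) {
    gap <- d$protein_start[-1L] - d$protein_end[-nrow(d)] - 1L
    if (any(gap < 0L)) {
      i <- which(gap < 0L)[1L]
      stop(sprintf("overlapping exon spans: exon %d ends at %d, exon %d starts at %d",
                   d$exon_number[i], d$protein_end[i],
                   d$exon_number[i + 1L], d$protein_start[i + 1L]),
           call. = FALSE)
    }
    if (require_contiguous && any(gap > 0L))
      stop("exon spans are not contiguous", call. = FALSE)
  }
  d$length_aa <- d$protein_end - d$protein_start + 1L
  d
}

#' Write an exon table (or any exon report) as TSV
#' @param exons A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_table <- function(exons, path) {
  utils::write.table(exons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Protein-residue exon spans from CDS exon lengths
#'
#' Convenience converter from a coding-sequence exon structure: given the
#' nucleotide length of the CDS portion of each exon (first to last coding
#' exon, in order), returns the 1-based inclusive protein-residue span that
#' each exon contributes to.  An exon whose CDS ends mid-codon is credited
#' with the split codon's residue; the next exon starts at the following
#' residue.  Genome-coordinate bookkeeping (strand, splice phases from GTF)
#' is out of scope: inputs are CDS lengths only.
#'
#' @param cds_lengths Integer vector of per-exon CDS lengths in nucleotides;
#'   must sum to a multiple of 3 (a terminal stop codon is tolerated).
#' @param exon_number Optional exon numbers (default `1:length(cds_lengths)`).
#' @return An exon `data.frame` (see [exon_table()]).
#' @export
exon_spans_from_cds <- function(cds_lengths, exon_number = NULL) {
  stopifnot(all(cds_lengths > 0))
  if (is.null(exon_number)) exon_number <- seq_along(cds_lengths)
  n <- length(cds_lengths)
  prot_end <- ceiling(cumsum(as.numeric(cds_lengths)) / 3)
  # drop a terminal stop codon if the CDS total includes one
  prot_end[n] <- floor(sum(cds_lengths) / 3)
  prot_start <- c(1, prot_end[-n] + 1)
  if (any(prot_start > prot_end))
    stop("an exon contributes no complete residue beyond the previous exon",
         call. = FALSE)
  exon_table(exon_number, prot_start, prot_end)
}
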