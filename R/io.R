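#' Read sequences from a FASTA file
#'
#' Reads plain or gapped FASTA into a tibble with one row per record.
#' Residues are folded to uppercase and `U` is mapped to `T` so that all
#' downstream identity comparisons work on a single alphabet.
#'
#' @param path Path to a FASTA file (plain or aligned; gaps `-` allowed).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty)
#'   and `seq` (uppercase residue string).
#' @details Duplicate record ids are an error: every downstream matrix and
#'   grouping operation keys on the id.
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records found in '", path, "'", call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty sequence id in '", path, "'", call. = FALSE)
  seqs <- chartr("u", "U", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  tibble::tibble(id = ids, description = desc, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id`, `seq` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seq_tbl(seqs)
  headers <- seqs$id
  if ("description" %in% names(seqs)) {
    has_desc <- nzchar(seqs$description)
    headers[has_desc] <- paste(seqs$id[has_desc], seqs$description[has_desc])
  }
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Coerce a user-supplied object to the internal sequence tibble shape.
as_seq_tbl <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_fasta(x))
  }
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    stop("expected a FASTA path or a data frame with columns 'id' and 'seq'",
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read a multiple sequence alignment from gapped FASTA
#'
#' Like [read_fasta()] but enforces the alignment contract: at least two
#' records, all of identical length.
#'
#' @inheritParams read_fasta
#' @return A tibble of class `gaoscope_alignment` with columns `id`,
#'   `description`, `seq`, and an `alignment_length` attribute.
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  as_alignment(seqs)
}

#' Validate a sequence table as an alignment
#'
#' @param seqs Data frame with `id` and `seq` columns (gapped allowed).
#' @return The input as a `gaoscope_alignment` tibble.
#' @export
as_alignment <- function(seqs) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) < 2L) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  lens <- nchar(seqs$seq)
  if (length(unique(lens)) != 1L) {
    ref <- stats::median(lens)
    bad <- seqs$id[lens != lens[1L]]
    stop("ragged alignment: sequence length differs for id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(seqs, "alignment_length") <- lens[1L]
  class(seqs) <- c("gaoscope_alignment", class(seqs))
  seqs
}

#' @export
print.gaoscope_alignment <- function(x, ...) {
  cat("# Alignment: ", nrow(x), " sequences x ",
      attr(x, "alignment_length"), " columns\n", sep = "")
  NextMethod()
}

#' Alignment length (columns)
#' @param aln A `gaoscope_alignment`.
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) {
  len <- attr(aln, "alignment_length")
  if (is.null(len)) len <- unique(nchar(aln$seq))
  as.integer(len[1L])
}

# Default roles for annotation-table columns; inputs modelled on merged
# Prokka + BlastKOALA gene tables. Headers are configurable because real
# supplementary tables vary.
default_annotation_cols <- function() {
  c(genome_id = "genome_id", gene_id = "gene_id", gene_symbol = "gene_symbol",
    product = "product", ko_id = "ko_id", start = "start", end = "end",
    strand = "strand")
}

#' Read a per-genome gene annotation table
#'
#' Parses a tab-delimited annotation table (one row per gene) combining
#' gene-product level annotation with KEGG Orthology (KO) assignments.
#' Coordinates are 1-based inclusive throughout the package.
#'
#' @param path Path to a TSV file with a header row.
#' @param col_map Named character vector mapping roles
#'   (`genome_id`, `gene_id`, `gene_symbol`, `product`, `ko_id`, `start`,
#'   `end`, `strand`) to the header names actually present in the file.
#'   Roles missing from the file (other than `gene_id`) become empty columns.
#' @param genome_id Optional genome id applied to every row when the file has
#'   no genome column.
#' @return A tibble with the eight role columns. KO ids that do not match
#'   `K` + 5 digits are blanked with a warning; empty KO cells are allowed.
#' @export
read_annotation_table <- function(path, col_map = default_annotation_cols(),
                                  genome_id = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  full_map <- default_annotation_cols()
  full_map[names(col_map)] <- col_map
  if (!full_map[["gene_id"]] %in% names(raw)) {
    stop("annotation table '", path, "' lacks mandatory gene id column '",
         full_map[["gene_id"]], "'", call. = FALSE)
  }
  get_col <- function(role) {
    nm <- full_map[[role]]
    if (nm %in% names(raw)) raw[[nm]] else rep("", nrow(raw))
  }
  out <- tibble::tibble(
    genome_id = get_col("genome_id"),
    gene_id = get_col("gene_id"),
    gene_symbol = get_col("gene_symbol"),
    product = get_col("product"),
    ko_id = get_col("ko_id"),
    start = suppressWarnings(as.integer(get_col("start"))),
    end = suppressWarnings(as.integer(get_col("end"))),
    strand = get_col("strand")
  )
  out <- dplyr::mutate(out, dplyr::across(
    c("genome_id", "gene_symbol", "product", "ko_id", "strand"),
    ~ dplyr::coalesce(.x, "")
  ))
  if (!is.null(genome_id)) out$genome_id <- genome_id
  bad_ko <- nzchar(out$ko_id) & !grepl("^K[0-9]{5}$", out$ko_id)
  if (any(bad_ko)) {
    warning("blanking ", sum(bad_ko), " malformed KO id(s), e.g. '",
            out$ko_id[which(bad_ko)[1L]], "'", call. = FALSE)
    out$ko_id[bad_ko] <- ""
  }
  both <- !is.na(out$start) & !is.na(out$end)
  if (any(both & out$end < out$start)) {
    stop("annotation rows with end < start in '", path, "'", call. = FALSE)
  }
  out
}

#' Write an annotation table to TSV
#' @param annotations Tibble as returned by [read_annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Read a KEGG-module definition table
#'
#' @param path TSV with header and columns `module_id`, `name`, `definition`
#'   and optionally `diagnostic_kos` (comma- or space-separated KO ids whose
#'   joint absence forces an 'absent' call, e.g. isocitrate lyase for the
#'   glyoxylate cycle).
#' @return A tibble with columns `module_id`, `name`, `definition` and a
#'   list-column `diagnostic_kos`. Module ids must be unique.
#' @export
read_module_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("module_id", "name", "definition")
  if (!all(need %in% names(raw))) {
    stop("module table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$module_id)) {
    dup <- unique(raw$module_id[duplicated(raw$module_id)])
    stop("duplicate module id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  diag_raw <- if ("diagnostic_kos" %in% names(raw)) raw$diagnostic_kos else
    rep("", nrow(raw))
  diag_raw[is.na(diag_raw)] <- ""
  tibble::tibble(
    module_id = raw$module_id,
    name = dplyr::coalesce(raw$name, ""),
    definition = raw$definition,
    diagnostic_kos = lapply(diag_raw, function(x) {
      kos <- unlist(strsplit(x, "[,;[:space:]]+"))
      kos[nzchar(kos)]
    })
  )
}

#' Read a per-base coverage track
#'
#' @param path Two-column TSV (`pos`, `depth`; header optional) with one row
#'   per base, positions 1-based and consecutive.
#' @param genome_id Optional genome label attached as an attribute.
#' @return A tibble with integer `pos` and numeric `depth`.
#' @export
read_coverage_track <- function(path, genome_id = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  raw <- readr::read_tsv(path, col_names = if (has_header) TRUE else
                           c("pos", "depth"),
                         col_types = "id", skip = 0L, progress = FALSE)
  names(raw)[1:2] <- c("pos", "depth")
  if (any(raw$depth < 0)) stop("negative depths in coverage track", call. = FALSE)
  out <- tibble::as_tibble(raw[, c("pos", "depth")])
  attr(out, "genome_id") <- genome_id
  out
}
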