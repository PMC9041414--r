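#' Define a gene panel for presence/absence screening
#'
#' @param panel Data frame with columns `gene_symbol` (unique), and
#'   optionally `ko_id`, `description`, `category`.
#' @return A validated tibble of class `gene_panel`.
#' @export
gene_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) == 0L || !"gene_symbol" %in% names(panel)) {
    stop("panel needs at least one row and a gene_symbol column",
         call. = FALSE)
  }
  if (anyDuplicated(panel$gene_symbol)) {
    stop("panel gene symbols must be unique", call. = FALSE)
  }
  for (col in c("ko_id", "description", "category")) {
    if (!col %in% names(panel)) panel[[col]] <- ""
    panel[[col]] <- dplyr::coalesce(panel[[col]], "")
  }
  panel <- panel[, c("gene_symbol", "ko_id", "description", "category")]
  class(panel) <- c("gene_panel", class(panel))
  panel
}

# Match annotation symbols against a panel symbol under a matching mode.
symbol_matches <- function(ann_symbols, panel_symbol, strip_suffix) {
  a <- tolower(ann_symbols)
  p <- tolower(panel_symbol)
  hit <- a == p
  if (strip_suffix) hit <- hit | sub("[0-9]+$", "", a) == p
  hit & nzchar(ann_symbols)
}

#' Gene presence/absence and copy-number matrix across genomes
#'
#' For every (panel gene, genome) pair, counts annotation rows matching the
#' panel entry. Matching is case-insensitive on gene symbol; in
#' `"symbol_suffix"` mode a trailing copy-number digit on the annotated
#' symbol is ignored (so glgB1/glgB2 match panel entry glgB, reflecting how
#' paralog families are tabulated); `"ko"` matches on the panel's KO id; and
#' `"any"` accepts either route, symbol first.
#'
#' @param annotations Annotation tibble covering one or more genomes
#'   (distinguished by `genome_id`).
#' @param panel A [gene_panel()] (or coercible data frame).
#' @param match_mode One of `"symbol_suffix"` (default), `"symbol"`,
#'   `"ko"`, `"any"`.
#' @param genomes Optional character vector fixing genome order.
#' @return A long tibble of class `presence_matrix` with `gene_symbol`,
#'   `genome_id`, `copies`, `present` plus the panel columns.
#' @export
build_presence_matrix <- function(annotations, panel,
                                  match_mode = c("symbol_suffix", "symbol",
                                                 "ko", "any"),
                                  genomes = NULL) {
  match_mode <- match.arg(match_mode)
  panel <- gene_panel(panel)
  ann <- tibble::as_tibble(annotations)
  genomes <- genomes %||% unique(ann$genome_id)
  if (length(genomes) == 0L) stop("no genomes in annotation input", call. = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    sym <- panel$gene_symbol[i]
    ko <- panel$ko_id[i]
    purrr::map_dfr(genomes, function(g) {
      rows <- ann[ann$genome_id == g, ]
      hit_sym <- switch(match_mode,
        symbol = symbol_matches(rows$gene_symbol, sym, FALSE),
        symbol_suffix = symbol_matches(rows$gene_symbol, sym, TRUE),
        ko = rep(FALSE, nrow(rows)),
        any = symbol_matches(rows$gene_symbol, sym, TRUE))
      hit_ko <- if (match_mode %in% c("ko", "any") && nzchar(ko)) {
        rows$ko_id == ko
      } else rep(FALSE, nrow(rows))
      copies <- sum(hit_sym | hit_ko)
      tibble::tibble(gene_symbol = sym, genome_id = g,
                     copies = as.integer(copies), present = copies >= 1L)
    })
  })
  out <- dplyr::left_join(out, as.data.frame(panel), by = "gene_symbol")
  out <- tibble::as_tibble(out)
  attr(out, "genomes") <- genomes
  attr(out, "match_mode") <- match_mode
  class(out) <- c("presence_matrix", class(out))
  out
}

#' Render a presence matrix as wide +/- and copy-number tables
#'
#' @param matrix A `presence_matrix` from [build_presence_matrix()].
#' @param path Optional TSV path for the +/- table; a companion
#'   `<path>.copies.tsv` holds the copy numbers.
#' @return A list with `presence` (wide tibble of `+`/`-` cells, one row per
#'   gene with its description first) and `copies` (wide integer tibble).
#' @export
render_presence_matrix <- function(matrix, path = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"))
  base <- matrix[, c("gene_symbol", "description", "genome_id")]
  base$cell <- ifelse(matrix$present, "+", "-")
  wide <- tidyr::pivot_wider(base, names_from = "genome_id",
                             values_from = "cell")
  cp <- matrix[, c("gene_symbol", "description", "genome_id", "copies")]
  wide_cp <- tidyr::pivot_wider(cp, names_from = "genome_id",
                                values_from = "copies")
  if (!is.null(path)) {
    readr::write_tsv(wide, path, progress = FALSE)
    readr::write_tsv(wide_cp, paste0(path, ".copies.tsv"), progress = FALSE)
  }
  list(presence = wide, copies = wide_cp)
}

#' Read a rendered +/- presence table back into long form
#'
#' Inverse of the presence half of [render_presence_matrix()]; used for
#' round-trip checks and for consuming published-style tables.
#'
#' @param path TSV written by [render_presence_matrix()].
#' @return A long tibble with `gene_symbol`, `genome_id`, `present`.
#' @export
read_presence_matrix <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  long <- tidyr::pivot_longer(wide, cols = -c("gene_symbol", "description"),
                              names_to = "genome_id", values_to = "cell")
  long$present <- long$cell == "+"
  long[, c("gene_symbol", "genome_id", "present")]
}
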