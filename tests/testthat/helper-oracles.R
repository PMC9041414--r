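# Independent brute-force oracle for the pairwise identity statistic:
# a plain column loop, sharing no code with the package implementation.
oracle_pid <- function(a, b, count_single_gaps = TRUE) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  num <- 0L
  den <- 0L
  for (i in seq_along(ca)) {
    ga <- ca[i] %in% c("-", ".")
    gb <- cb[i] %in% c("-", ".")
    if (ga && gb) next                       # shared indel: excluded
    if (!count_single_gaps && (ga || gb)) next
    den <- den + 1L
    if (!ga && !gb && ca[i] == cb[i] && ca[i] %in% c("A", "C", "G", "T")) {
      num <- num + 1L
    }
  }
  if (den == 0L) stop("undefined")
  num / den
}

# Random gapped alignment generator for oracle comparisons.
random_gapped_alignment <- function(n_seq, n_col, gap_prob = 0.1) {
  seqs <- replicate(n_seq, {
    chars <- sample(c("A", "C", "G", "T", "-"), n_col, replace = TRUE,
                    prob = c(rep((1 - gap_prob) / 4, 4), gap_prob))
    paste(chars, collapse = "")
  })
  as_alignment(tibble::tibble(id = sprintf("s%02d", seq_len(n_seq)),
                              description = "", seq = seqs))
}

# Hand-written boolean evaluators for test module definitions, used as
# truth-table oracles for the DEFINITION parser/evaluator. Each returns the
# per-block satisfaction vector for a given KO set.
oracle_module_blocks <- list(
  # "K00001 K00002"
  two_step = function(kos) c("K00001" %in% kos, "K00002" %in% kos),
  # "K00001 (K00002,K00003) K00004+K00005"
  mixed = function(kos) c(
    "K00001" %in% kos,
    ("K00002" %in% kos) || ("K00003" %in% kos),
    ("K00004" %in% kos) && ("K00005" %in% kos)
  ),
  # "K00001 -K00002" (optional component is not a block)
  optional = function(kos) c("K00001" %in% kos),
  # "(K00001,K00002) (K00003 K00004),K00005"
  nested = function(kos) c(
    ("K00001" %in% kos) || ("K00002" %in% kos),
    (("K00003" %in% kos) && ("K00004" %in% kos)) || ("K00005" %in% kos)
  ),
  # "K00001+K00002-K00003 -- K00004,K00005+K00006"
  gapmarker = function(kos) c(
    ("K00001" %in% kos) && ("K00002" %in% kos),
    TRUE,
    ("K00004" %in% kos) ||
      (("K00005" %in% kos) && ("K00006" %in% kos))
  )
)

oracle_module_defs <- c(
  two_step = "K00001 K00002",
  mixed = "K00001 (K00002,K00003) K00004+K00005",
  optional = "K00001 -K00002",
  nested = "(K00001,K00002) (K00003 K00004),K00005",
  gapmarker = "K00001+K00002-K00003 -- K00004,K00005+K00006"
)

oracle_ko_universe <- paste0("K0000", 1:6)

# A 5-block glycogen-biosynthesis-style module (linear chain of steps,
# one with an alternative), plus a glyoxylate-style module whose
# non-diagnostic KOs are shared with another pathway.
glycogen_style_module <- function() {
  parse_module_definition(
    "K00001 K00002 (K00003,K00004) K00005 K00006",
    module_id = "M90001", name = "glycogen-biosynthesis-style")
}

glyoxylate_style_module <- function() {
  parse_module_definition(
    "K01637 K01638 K00024 K01681",
    module_id = "M90012", name = "glyoxylate-style",
    diagnostic_kos = c("K01637", "K01638"))
}

annotation_row <- function(genome, gene, ko = "", symbol = "",
                           product = "", start = NA_integer_,
                           end = NA_integer_) {
  tibble::tibble(genome_id = genome, gene_id = gene, gene_symbol = symbol,
                 product = product, ko_id = ko, start = start, end = end,
                 strand = "")
}

profile_from_kos <- function(kos, genome = "g1") {
  ann <- if (length(kos) == 0L) annotation_row(genome, "GENE_0000")[0, ]
  else purrr::map_dfr(seq_along(kos), function(i) {
    annotation_row(genome, sprintf("GENE_%04d", i), ko = kos[i])
  })
  ko_profile(ann, genome)
}
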