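test_that("DEFINITION grammar parses blocks, alternatives, complexes", {
  m1 <- parse_module_definition("K00001 K00002")
  expect_length(m1$blocks, 2L)
  m2 <- parse_module_definition("K00001 (K00002,K00003) K00004+K00005")
  expect_length(m2$blocks, 3L)
  expect_setequal(m2$ko_universe, paste0("K0000", 1:5))
  # block 2 satisfied by either alternative; block 3 needs both subunits
  expect_equal(count_missing_blocks(m2, c("K00001", "K00003", "K00004")), 1L)
  expect_equal(count_missing_blocks(m2, c("K00001", "K00003", "K00004",
                                          "K00005")), 0L)
  # optional component is not a required block
  m3 <- parse_module_definition("K00001 -K00002")
  expect_length(m3$blocks, 1L)
  expect_equal(count_missing_blocks(m3, "K00001"), 0L)
  # gap marker is an always-satisfied block
  m4 <- parse_module_definition("K00001 -- K00002")
  expect_length(m4$blocks, 3L)
  expect_equal(count_missing_blocks(m4, character(0)), 2L)
  expect_error(parse_module_definition("K00001 (K00002"), "parenthes")
  expect_error(parse_module_definition(""), "empty")
})

test_that("parse -> unparse -> parse is a fixed point", {
  for (def in unname(oracle_module_defs)) {
    m <- parse_module_definition(def)
    un <- unparse_module_definition(m)
    m2 <- parse_module_definition(un)
    expect_identical(m$tree, m2$tree, label = def)
    expect_identical(un, unparse_module_definition(m2))
  }
})

test_that("block evaluation matches hand-written truth tables over all 2^6 subsets", {
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  for (name in names(oracle_module_defs)) {
    mod <- parse_module_definition(oracle_module_defs[[name]])
    oracle <- oracle_module_blocks[[name]]
    for (r in seq_len(nrow(subsets))) {
      kos <- oracle_ko_universe[unlist(subsets[r, ])]
      expect_equal(count_missing_blocks(mod, kos),
                   sum(!oracle(kos)),
                   label = paste(name, paste(kos, collapse = ",")))
    }
  }
})

test_that("adding a KO never increases the missing-block count", {
  set.seed(31)
  for (name in names(oracle_module_defs)) {
    mod <- parse_module_definition(oracle_module_defs[[name]])
    for (i in 1:20) {
      kos <- sample(oracle_ko_universe, sample(0:5, 1))
      extra <- sample(setdiff(oracle_ko_universe, kos), 1)
      expect_lte(count_missing_blocks(mod, c(kos, extra)),
                 count_missing_blocks(mod, kos))
    }
  }
})

test_that("status classification follows the four-level scheme", {
  glyc <- glycogen_style_module()
  # fully satisfied 5-block module with 5 genes -> complete
  p5 <- profile_from_kos(c("K00001", "K00002", "K00003", "K00005", "K00006"))
  call <- classify_status(glyc, p5)
  expect_equal(call$status, "C")
  expect_equal(call$genes_detected, 5L)
  expect_equal(call$cell, "C | 5")
  # exactly 2 missing blocks -> largely intact '+'
  p3 <- profile_from_kos(c("K00001", "K00002", "K00003"))
  expect_equal(classify_status(glyc, p3)$status, "+")
  expect_equal(classify_status(glyc, p3)$missing_blocks, 2L)
  # 3 missing blocks -> incomplete '?'
  p2 <- profile_from_kos(c("K00001", "K00002"))
  expect_equal(classify_status(glyc, p2)$status, "?")
  # nothing detected -> absent
  p0 <- profile_from_kos(character(0))
  call0 <- classify_status(glyc, p0)
  expect_equal(call0$status, "-")
  expect_equal(call0$genes_detected, 0L)
})

test_that("diagnostic-gene override declares shared-enzyme modules absent", {
  glyox <- glyoxylate_style_module()
  # all shared TCA enzymes present but no diagnostic KO -> '-' with 2 genes
  shared <- profile_from_kos(c("K00024", "K01681"))
  call <- classify_status(glyox, shared)
  expect_equal(call$status, "-")
  expect_true(call$override_applied)
  expect_equal(call$genes_detected, 2L)
  # with the diagnostic isocitrate-lyase-style KO present the override lifts
  full <- profile_from_kos(c("K01637", "K01638", "K00024", "K01681"))
  call2 <- classify_status(glyox, full)
  expect_equal(call2$status, "C")
  expect_false(call2$override_applied)
})

test_that("paralogs count with multiplicity in genes_detected", {
  mod <- parse_module_definition("K00001 K00002", module_id = "M1")
  ann <- dplyr::bind_rows(
    annotation_row("g1", "G1", ko = "K00001"),
    annotation_row("g1", "G2", ko = "K00001"),
    annotation_row("g1", "G3", ko = "K00002"))
  call <- classify_status(mod, ko_profile(ann, "g1"))
  expect_equal(call$genes_detected, 3L)
  expect_equal(call$cell, "C | 3")
})

test_that("rescue adds hidden KOs, is idempotent and never lowers status", {
  mod <- parse_module_definition("K14451 K00001", module_id = "M373")
  ann <- dplyr::bind_rows(
    annotation_row("g1", "CDGBEKEE_03341", symbol = "mcl2",
                   product = "malyl-CoA thioesterase"),
    annotation_row("g1", "CDGBEKEE_00001", ko = "K00001"))
  rules <- tibble::tibble(match_on = "product_regex",
                          pattern = "malyl-CoA thioesterase",
                          target_ko = "K14451")
  p0 <- ko_profile(ann, "g1")
  expect_equal(classify_status(mod, p0)$status, "+")
  p1 <- apply_rescue(p0, ann, rules)
  expect_true("K14451" %in% p1$kos)
  expect_equal(unname(p1$provenance_by_ko["K14451"]), "rescued")
  expect_equal(classify_status(mod, p1)$status, "C")
  expect_equal(classify_status(mod, p1)$rescued_kos, "K14451")
  # idempotence
  p2 <- apply_rescue(p1, ann, rules)
  expect_identical(p1, p2)
  # gene-symbol rule route (glgX-style rescue)
  rules2 <- tibble::tibble(match_on = "gene_symbol", pattern = "glgX",
                           target_ko = "K01214")
  ann2 <- annotation_row("g1", "CDGBEKEE_01736", symbol = "glgX",
                         product = "glycogen debranching enzyme")
  p3 <- apply_rescue(ko_profile(ann2, "g1"), ann2, rules2)
  expect_true("K01214" %in% p3$kos)
  # non-matching rules are no-ops
  p4 <- apply_rescue(p0, ann, tibble::tibble(match_on = "gene_symbol",
                                             pattern = "nope",
                                             target_ko = "K99999"))
  expect_identical(p0$kos, p4$kos)
})

test_that("completeness matrix covers all module x genome combinations", {
  mods <- tibble::tibble(
    module_id = c("M1", "M2"), name = c("one", "two"),
    definition = c("K00001 K00002", "K00003"),
    diagnostic_kos = list(character(0), character(0)))
  ann <- dplyr::bind_rows(
    annotation_row("g1", "A1", ko = "K00001"),
    annotation_row("g1", "A2", ko = "K00002"),
    annotation_row("g2", "B1", ko = "K00003"),
    annotation_row("g3", "C1", ko = "K00001"))
  calls <- completeness_matrix(mods, ann)
  expect_equal(nrow(calls), 6L)
  expect_equal(calls$status[calls$module_id == "M1" & calls$genome_id == "g1"],
               "C")
  expect_equal(calls$status[calls$module_id == "M2" & calls$genome_id == "g1"],
               "-")
  wide <- render_completeness(calls)
  expect_equal(dim(wide), c(2L, 4L))
  expect_equal(wide$g1[wide$module_id == "M1"], "C | 2")
})
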