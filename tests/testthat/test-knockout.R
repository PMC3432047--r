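test_that("gene associations follow isozyme (or) / complex (and) semantics", {
  expect_false(evaluate_gene_association("gA", "gA"))
  expect_true(evaluate_gene_association("gA or gB", "gA"))
  expect_false(evaluate_gene_association("gA and gB", "gB"))
  expect_true(evaluate_gene_association("(gA and gB) or gC", "gA"))
  expect_false(evaluate_gene_association("(gA and gB) or gC", c("gB", "gC")))
  expect_true(evaluate_gene_association(NA_character_, "gA"))
  expect_error(evaluate_gene_association("gA &&& gB", "gA"), "malformed")
  # expressed-gene whitelist: unlisted genes count as absent
  expect_false(evaluate_gene_association("gA", character(0),
                                         expressed_genes = "gB"))
})

test_that("single-gene scan bins biomass fractions and tolerates unused genes", {
  model <- ccm()
  cons <- ccm_glc_constraints()
  wt <- ccm_glc_wt()
  scan <- single_gene_deletion_scan(model, cons, method = "moma",
                                    genes = c("SSOg49", "SSOg03", "SSOg04"),
                                    wildtype = wt)
  expect_equal(scan$status, rep("ok", 3))
  by_gene <- stats::setNames(scan$category, scan$gene)
  expect_equal(unname(by_gene["SSOg49"]), "unaffected")  # zero wild-type flux
  expect_equal(unname(by_gene["SSOg03"]), "lethal")
  expect_equal(unname(by_gene["SSOg04"]), "impaired")    # branch redundancy
  expect_true(all(scan$biomass_fraction >= 0 & scan$biomass_fraction <= 1 + 1e-6))
})

test_that("scan results are independent of gene order and FBA-lethal implies MOMA-lethal", {
  model <- ccm()
  cons <- ccm_glc_constraints()
  wt <- ccm_glc_wt()
  genes <- c("SSOg03", "SSOg49", "SSOg08", "SSOg04")
  a <- single_gene_deletion_scan(model, cons, genes = genes, wildtype = wt)
  b <- single_gene_deletion_scan(model, cons, genes = rev(genes), wildtype = wt)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$biomass_fraction, b$biomass_fraction, tolerance = 1e-9)

  fba_scan <- single_gene_deletion_scan(model, cons, method = "fba",
                                        genes = genes, wildtype = wt)
  moma_scan <- a
  fba_lethal <- fba_scan$gene[fba_scan$category == "lethal"]
  moma_lethal <- moma_scan$gene[moma_scan$category == "lethal"]
  expect_true(all(fba_lethal %in% moma_lethal))
})

test_that("essentiality summary returns fractions that sum to one", {
  fake <- data.frame(gene = letters[1:10],
                     reactions = "", biomass_fraction = c(rep(0, 2), rep(1, 8)),
                     category = c(rep("lethal", 2), rep("unaffected", 8)),
                     status = "ok")
  s <- essentiality_summary(fake)
  expect_equal(unname(s["lethal"]), 0.2)
  expect_equal(sum(s), 1)
  all_un <- fake; all_un$category <- "unaffected"
  expect_equal(unname(essentiality_summary(all_un)["unaffected"]), 1)
})
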