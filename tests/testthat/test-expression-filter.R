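make_ft <- function() {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    length = c(1000, 2000, 1500, 500, 3000, 1000, 1200, 800, 2500, 600),
    log2fc = c(0.60, 0.50, -0.9, 0.1, NA, 0.585, -0.585, 2.0, 0.3, -1.2),
    padj = c(0.01, 0.001, 0.04, 0.2, NA, 0.05, 0.06, 0.001, 0.04, 0.01),
    is_rrna = c(rep(FALSE, 8), TRUE, TRUE),
    metabolic = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  counts <- matrix(rep(c(100, 100, 50, 5, 80, 200, 120, 60, 5000, 4000), 4),
                   ncol = 4, dimnames = list(genes$gene_id, paste0("s", 1:4)))
  feature_table(genes, counts)
}

test_that("rRNA removal drops flagged records and keeps samples", {
  ft <- make_ft()
  out <- remove_rrna(ft)
  expect_equal(nrow(out$genes), 8)
  expect_false(any(out$genes$is_rrna))
  expect_identical(colnames(out$counts), colnames(ft$counts))

  none <- ft
  none$genes$is_rrna <- FALSE
  expect_equal(nrow(remove_rrna(none)$genes), 10)

  all_flagged <- ft
  all_flagged$genes$is_rrna <- TRUE
  expect_warning(empty <- remove_rrna(all_flagged), "empty")
  expect_equal(nrow(empty$genes), 0)
})

test_that("TPM normalizes for length and depth and sums to one million", {
  genes <- data.frame(gene_id = c("a", "b"), length = c(1000, 2000))
  counts <- matrix(c(10, 10, 400, 400), ncol = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  ft <- tpm(feature_table(genes, counts))
  # equal counts, double length -> 2:1 TPM split
  expect_equal(ft$tpm[, "s1"], c(a = 2e6 / 3, b = 1e6 / 3))
  # depth invariance: scaling a sample's counts changes nothing
  expect_equal(ft$tpm[, "s2"], ft$tpm[, "s1"])
  expect_equal(unname(colSums(ft$tpm)), c(1e6, 1e6))

  # single gene takes the whole million
  single <- tpm(feature_table(data.frame(gene_id = "a", length = 700),
                              matrix(3, 1, 1, dimnames = list("a", "s1"))))
  expect_equal(unname(single$tpm[1, 1]), 1e6)

  zero <- feature_table(genes, matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(tpm(zero), "zero total")

  big <- tpm(simulate_feature_table(seed = 2))
  expect_equal(unname(colSums(big$tpm)), rep(1e6, ncol(big$counts)),
               tolerance = 1e-6)
})

test_that("top-gene ranking is deterministic and respects the gene set", {
  ft <- tpm(make_ft())
  top <- top_metabolic_genes(ft, "metabolic", paste0("s", 1:4), k = 3)
  expect_equal(nrow(top), 3)
  expect_true(all(diff(top$mean_tpm) <= 0))
  expect_true(all(top$gene_id %in% ft$genes$gene_id[ft$genes$metabolic]))

  # k larger than the set: whole set, still sorted
  all6 <- top_metabolic_genes(ft, "metabolic", "s1", k = 100)
  expect_equal(nrow(all6), sum(ft$genes$metabolic))

  # permuting the record order does not change the output
  perm <- subset_perm <- ft
  idx <- rev(seq_len(nrow(ft$genes)))
  perm$genes <- ft$genes[idx, ]; perm$counts <- ft$counts[idx, ]
  perm$tpm <- ft$tpm[idx, ]
  expect_equal(top_metabolic_genes(perm, "metabolic", "s1", k = 3),
               top_metabolic_genes(ft, "metabolic", "s1", k = 3))

  # ties break lexicographically by gene_id
  tie <- feature_table(
    data.frame(gene_id = c("zz", "aa"), length = c(1000, 1000),
               set = c(TRUE, TRUE)),
    matrix(c(5, 5), 2, 1, dimnames = list(c("zz", "aa"), "s1"))
  )
  expect_equal(top_metabolic_genes(tie, "set", "s1", k = 2)$gene_id,
               c("aa", "zz"))

  expect_error(top_metabolic_genes(ft, "nope", "s1"), "unknown gene set")
  expect_error(top_metabolic_genes(ft, "metabolic", character(0)),
               "non-empty")
})

test_that("DE filter applies inclusive thresholds and drops missing stats", {
  ft <- make_ft()
  kept <- de_filter(ft)$genes$gene_id
  # g01: log2fc 0.60, padj 0.01 -> kept; g02: fc 0.50 below threshold -> out
  expect_true("g01" %in% kept)
  expect_false("g02" %in% kept)
  # inclusive boundaries: |fc| = 0.585 and padj = 0.05 pass
  expect_true("g06" %in% kept)
  # padj 0.06 fails
  expect_false("g07" %in% kept)
  # NA statistics are excluded
  expect_false("g05" %in% kept)
  expect_setequal(kept, c("g01", "g03", "g06", "g08", "g10"))

  empty <- subset(ft$genes, FALSE)
  eft <- feature_table(empty, ft$counts[0, , drop = FALSE])
  expect_equal(nrow(de_filter(eft)$genes), 0)
})

test_that("abundance floor keeps genes clearing the threshold in any group", {
  genes <- data.frame(gene_id = c("lo", "mid", "hi"), length = rep(1000, 3))
  # three samples = three "time point" groups
  counts <- matrix(c(1, 1, 1,
                     10, 60, 5,
                     500, 500, 500), nrow = 3, byrow = TRUE,
                   dimnames = list(genes$gene_id, c("t1", "t2", "t3")))
  ft <- tpm(feature_table(genes, counts))
  groups <- list("t1", "t2", "t3")

  kept <- abundance_floor(ft, groups, min_mean_tpm = 50)$genes$gene_id
  expect_setequal(kept, c("lo", "mid", "hi"))  # shares of a 3-gene library are large

  # with a floor just above a gene's best group mean it is dropped
  best_mid <- max(ft$tpm["mid", ])
  expect_false("mid" %in%
                 abundance_floor(ft, groups, best_mid + 1)$genes$gene_id)
  # zero floor is the identity
  expect_equal(abundance_floor(ft, groups, 0)$genes$gene_id, genes$gene_id)
  expect_error(abundance_floor(ft, list(character(0))), "empty")
})

test_that("DE and abundance filters commute and are idempotent", {
  ft <- tpm(simulate_feature_table(n_genes = 300, seed = 4))
  groups <- list(paste0("sample_", 1:3), paste0("sample_", 4:6))
  a <- abundance_floor(de_filter(ft), groups)
  b <- de_filter(abundance_floor(ft, groups))
  expect_equal(a$genes$gene_id, b$genes$gene_id)
  expect_equal(de_filter(a)$genes$gene_id, a$genes$gene_id)
  expect_equal(abundance_floor(a, groups)$genes$gene_id, a$genes$gene_id)
})
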