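test_that("substitution index is the fixed 12-category bijection", {
  expect_equal(substitution_index("C", "T"), 5)
  expect_equal(substitution_index("T", "G"), 11)
  expect_equal(substitution_index("A", "C"), 0)
  # exhaustive bijection over the 12 ordered pairs
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  idx <- substitution_index(pairs$ref, pairs$alt)
  expect_setequal(idx, 0:11)
  expect_equal(length(substitution_labels()), 12)
  expect_error(substitution_index("A", "A"), "differ")
  expect_error(substitution_index("N", "A"), "single bases")
})

test_that("gene signatures tally counts for the ranked top genes", {
  recs <- toy_records(gene = c("TP53", "TP53", "TP53", "TP53", "KRAS", "KRAS"),
                      ref  = c("C", "C", "C", "G", "A", "A"),
                      alt  = c("T", "T", "T", "A", "T", "T"))
  gs <- build_gene_signature(recs, top_k = 2)
  expect_equal(gs$genes, c("TP53", "KRAS"))
  expect_equal(gs$matrix[1, 6], 3)  # TP53 C>T (index 5, col 6)
  expect_equal(gs$matrix[1, 7], 1)  # TP53 G>A
  expect_equal(gs$matrix[2, 3], 2)  # KRAS A>T
  expect_equal(sum(gs$matrix), 6)
  expect_equal(length(gs$x_g), 24)
  # row-major flattening: first 12 entries are TP53's row
  expect_equal(gs$x_g[1:12], unname(gs$matrix[1, ]))

  gs25 <- build_gene_signature(recs, top_k = 25)
  expect_equal(length(gs25$x_g), 300)
  expect_equal(sum(rowSums(gs25$matrix) > 0), 2)  # 23 zero-padded rows

  # alphabetical tie-break at equal counts
  ties <- toy_records(gene = c("ZZZ", "AAA", "MMM", "AAA", "ZZZ", "MMM"))
  expect_equal(build_gene_signature(ties, top_k = 3)$genes,
               c("AAA", "MMM", "ZZZ"))

  expect_warning(gs0 <- build_gene_signature(toy_records()[0, ]), "empty")
  expect_equal(sum(gs0$matrix), 0)
  expect_equal(length(gs0$x_g), 300)
})

test_that("chromosome signatures are length-normalized counts", {
  lens <- stats::setNames(rep(1000, 24), chromosome_labels())
  recs <- toy_records(gene = c("G1", "G1"), chromosome = c("1", "1"),
                      ref = c("C", "C"), alt = c("T", "T"))
  cs <- build_chromosome_signature(recs, lengths = lens)
  expect_equal(cs$matrix["1", "C>T"], 2 / 1000)
  expect_equal(sum(cs$matrix), 2 / 1000)
  expect_equal(length(cs$x_c), 288)
  # row-major: entries 1..12 are chromosome 1
  expect_equal(cs$x_c[1:12], unname(cs$matrix["1", ]))

  # doubling lengths halves every entry
  cs2 <- build_chromosome_signature(recs, lengths = lens * 2)
  expect_equal(cs2$matrix, cs$matrix / 2)

  # empty records -> all-zero 24 x 12
  cs0 <- build_chromosome_signature(toy_records()[0, ], lengths = lens)
  expect_equal(dim(cs0$matrix), c(24, 12))
  expect_equal(sum(cs0$matrix), 0)

  # homogeneity: c-fold replication scales x_c by c
  rep3 <- recs[rep(seq_len(nrow(recs)), 3), ]
  cs3 <- build_chromosome_signature(rep3, lengths = lens)
  expect_equal(cs3$x_c, 3 * cs$x_c)
})

test_that("signatures are invariant to record order and conserve counts", {
  set.seed(3)
  out <- filter_records(random_records(500, seed = 3))
  recs <- out$records[out$records$cohort == "A", ]
  gs1 <- build_gene_signature(recs)
  cs1 <- build_chromosome_signature(recs)
  shuf <- recs[sample(nrow(recs)), ]
  expect_equal(build_gene_signature(shuf)$matrix, gs1$matrix)
  expect_equal(build_chromosome_signature(shuf)$matrix, cs1$matrix)
  # count conservation: signature total + off-top-k records = cohort total
  off_top <- sum(!recs$gene %in% gs1$genes)
  expect_equal(sum(gs1$matrix) + off_top, nrow(recs))
})

test_that("restrict_to_top_genes limits the chromosome tally", {
  recs <- toy_records(gene = c("A1", "A1", "A1", "B2", "B2", "C3"))
  cs_all <- build_chromosome_signature(recs)
  cs_top <- build_chromosome_signature(recs, restrict_to_top_genes = TRUE,
                                       top_k = 2)
  n_of <- function(cs) sum(cs$matrix * as.numeric(grch38_chrom_lengths()))
  expect_equal(round(n_of(cs_all)), 6)
  expect_equal(round(n_of(cs_top)), 5)  # C3 excluded
})

test_that("feature views align cohorts and scaling round-trips", {
  ds <- generate_dataset(synth_config(n_cohorts = 6, burden = c(400, 300),
                                      seed = 5))
  parts <- views_from_dataset(ds)
  v <- parts$views
  expect_equal(dim(v$Xg), c(6, 300))
  expect_equal(dim(v$Xc), c(6, 288))
  expect_equal(rownames(v$Xg), v$cohorts)
  for (method in c("log1p_center", "log1p_zscore")) {
    vv <- assemble_feature_views(parts$gene_sigs, parts$chrom_sigs,
                                 scaling = method)
    expect_lt(max(abs(unscale_view(vv, vv$Xg, "gene") - vv$Xg_raw)), 1e-8)
    expect_lt(max(abs(scale_view(vv, vv$Xg_raw, "gene") - vv$Xg)), 1e-10)
    # constant features carry no signal after scaling
    const_cols <- apply(vv$Xg_raw, 2, function(x) length(unique(x)) == 1)
    expect_true(all(abs(vv$Xg[, const_cols]) < 1e-12))
  }
  # cohort present in only one view is an error
  expect_error(assemble_feature_views(parts$gene_sigs[-1], parts$chrom_sigs),
               "cohorts differ")
})
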