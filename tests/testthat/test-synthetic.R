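test_that("generated trees are ultrametric, unit depth, and seed-stable", {
  for (n in c(3, 8, 20)) {
    tr <- gen_tree(n, seed = 1)
    expect_equal(length(tr$tip.label), n)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_true(all(abs(depths - 1) < 1e-12))
  }
  expect_identical(ape::write.tree(gen_tree(8, seed = 4)),
                   ape::write.tree(gen_tree(8, seed = 4)))
  expect_false(identical(ape::write.tree(gen_tree(8, seed = 4)),
                         ape::write.tree(gen_tree(8, seed = 5))))
  expect_error(gen_tree(2), "at least 3")
})

test_that("Brownian simulation has the analytic tip covariance", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # sigma2 = 0 degenerates to the root value
  expect_equal(unname(sim_bm(tr, 3.5, 0, seed = 1)), rep(3.5, 3))

  set.seed(90)
  reps <- t(replicate(2000, sim_bm(tr, 0, 1, lambda = 1)))
  expect_equal(unname(cov(reps)[, "A"]["B"]), 1, tolerance = 0.15)
  expect_equal(unname(var(reps[, "A"])), 2, tolerance = 0.15)

  set.seed(91)
  reps0 <- t(replicate(2000, sim_bm(tr, 0, 1, lambda = 0)))
  expect_lt(abs(cor(reps0[, "A"], reps0[, "B"])), 0.08)
})

test_that("planted density classes shape the trait-density relation", {
  tr <- gen_tree(32, seed = 7)
  logy <- sim_bm(tr, log(28), 0.6, 1, seed = 8)
  # no noise: null is constant, positive is a perfect monotone map
  d_null <- gen_locus_density(logy, "null", phylo_sd = 0, iid_sd = 0, tree = tr)
  expect_equal(unname(d_null), rep(d_null[[1]], 32))
  d_pos <- gen_locus_density(logy, "positive", phylo_sd = 0, iid_sd = 0, tree = tr)
  expect_equal(unname(cor(d_pos, logy, method = "spearman")), 1)
  d_neg <- gen_locus_density(logy, "negative", phylo_sd = 0, iid_sd = 0, tree = tr)
  expect_equal(unname(cor(d_neg, logy, method = "spearman")), -1)
  # clamping warning when the effect is absurdly strong
  expect_warning(gen_locus_density(logy, "positive", beta = 5,
                                   phylo_sd = 0, iid_sd = 0, tree = tr),
                 "clamping")
})

test_that("sequences realize the requested CpG count exactly", {
  expect_equal(cpg_count(density_to_sequence(0, 100, seed = 1)), 0L)
  expect_equal(cpg_count(density_to_sequence(0.1, 100, seed = 7)), 10L)
  expect_error(density_to_sequence(0.6, 10), "density")

  set.seed(33)
  for (i in 1:150) {
    len <- sample(50:700, 1)
    dens <- runif(1, 0, 0.25)
    # GC target must at least cover the bases inside the CpGs themselves
    gc <- runif(1, max(35, 200 * dens + 5), 70)
    s <- density_to_sequence(dens, len, gc)
    expect_equal(cpg_count(s), round(dens * len))
    expect_equal(nchar(s), len)
    expect_lt(abs(gc_content(s) - gc), 2.5)
  }
  # an unreachable GC target still realizes the exact count, with a warning
  expect_warning(s <- density_to_sequence(0.4, 100, gc_target = 40), "unreachable")
  expect_equal(cpg_count(s), 40L)
})

test_that("emitted datasets are reproducible and internally consistent", {
  cfg <- sim_config(n_tips = 8, n_loci = 6, prop_pos = 0.5, prop_neg = 0.5,
                    seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1); emit_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  tru <- read.delim(file.path(d1, "truth.tsv"))
  expect_equal(tru$cpg_count_realized,
               round(tru$density_true * cfg$seq_len))
  expect_equal(sum(unique(tru[, c("locus", "class")])$class == "positive"), 3)

  traits <- read_trait_table(file.path(d1, "traits.csv"), overrides = c())
  expect_true(all(traits$max_lifespan_yrs > 0))
  sim <- sim_density_dataset(cfg)
  expect_equal(log(traits$max_lifespan_yrs),
               unname(sim$log_lifespan[traits$species]), tolerance = 1e-12)

  # the FASTA sequences reproduce the quantized planted densities
  seqs <- read_fasta(file.path(d1, "loci", "P1.fa"))
  expect_equal(unname(cpg_count(seqs) / cfg$seq_len),
               unname(sim$density_quantized[1, names(seqs)]))
})

test_that("hit-table decoys and duplicates are removed by the filter chain", {
  cfg <- sim_config(n_tips = 6, n_loci = 10, decoy_frac = 0.5, dup_frac = 0.5,
                    seed = 44)
  dir <- withr::local_tempdir()
  emit_dataset(cfg, dir)
  files <- list.files(file.path(dir, "hits"), full.names = TRUE)
  hits <- do.call(rbind, lapply(files, function(f)
    read_blast_tab(f, sub("\\.tsv$", "", basename(f)))))
  expect_gt(nrow(hits), 60)  # decoys + duplicates present
  culled <- filter_identity(best_hit_per_species(hits), 70)
  expect_equal(nrow(culled), 60)
  expect_true(all(culled$subject_acc == "chr1"))
  # survivors carry the true sequences from the emitted FASTA
  seqs <- read_fasta(file.path(dir, "loci", "P01.fa"))
  p1 <- culled[culled$query_id == "P01", ]
  expect_identical(sort(p1$s_seq), sort(unname(seqs[p1$species])))
})
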