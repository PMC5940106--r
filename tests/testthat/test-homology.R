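test_that("best-hit culling applies the full tie-break chain", {
  # bitscore dominates
  h <- rbind(make_hit(bitscore = 200, subject_acc = "keep"),
             make_hit(bitscore = 180, subject_acc = "drop"))
  expect_equal(best_hit_per_species(h)$subject_acc, "keep")

  # bitscore tie -> min evalue
  h <- rbind(make_hit(evalue = 1e-60, subject_acc = "keep"),
             make_hit(evalue = 1e-50, subject_acc = "drop"))
  expect_equal(best_hit_per_species(h)$subject_acc, "keep")

  # then max aln_len, then subject_acc, then s_start
  h <- rbind(make_hit(aln_len = 10L, subject_acc = "drop", s_seq = "ACGTACGTAC"),
             make_hit(aln_len = 12L, subject_acc = "keep"))
  expect_equal(best_hit_per_species(h)$subject_acc, "keep")
  h <- rbind(make_hit(subject_acc = "chrB"), make_hit(subject_acc = "chrA"))
  expect_equal(best_hit_per_species(h)$subject_acc, "chrA")
  h <- rbind(make_hit(s_start = 500L), make_hit(s_start = 10L))
  expect_equal(best_hit_per_species(h)$s_start, 10L)

  # different species both survive
  h <- rbind(make_hit(species = "a"), make_hit(species = "b"))
  expect_equal(nrow(best_hit_per_species(h)), 2L)
})

test_that("best-hit culling is idempotent and order-independent", {
  set.seed(11)
  h <- do.call(rbind, lapply(1:40, function(i)
    make_hit(query_id = sample(c("P1", "P2"), 1),
             species = sample(c("a", "b", "c"), 1),
             bitscore = sample(100:300, 1), evalue = 10^-sample(20:80, 1),
             s_start = sample(1e5, 1))))
  b1 <- best_hit_per_species(h)
  expect_identical(best_hit_per_species(b1), b1)
  for (i in 1:5) {
    b2 <- best_hit_per_species(h[sample(nrow(h)), ])
    expect_identical(b2, b1)
  }
})

test_that("identity filtering uses >= and tier counts are cumulative", {
  h <- rbind(make_hit(pct_identity = 69.99), make_hit(pct_identity = 70))
  expect_equal(nrow(filter_identity(h, 70)), 1L)

  h <- rbind(make_hit(pct_identity = 71), make_hit(pct_identity = 96),
             make_hit(pct_identity = 99.5))
  expect_equal(unname(tier_counts(h)), c(3L, 2L, 2L, 1L))

  h <- rbind(make_hit(pct_identity = 100), make_hit(pct_identity = 100))
  expect_equal(unname(tier_counts(h)), rep(2L, 4))

  # monotone nonincreasing on random identities
  set.seed(3)
  h <- do.call(rbind, lapply(runif(50, 50, 100), function(p)
    make_hit(pct_identity = p)))
  tc <- tier_counts(h)
  expect_true(all(diff(tc) <= 0))

  expect_error(filter_identity(h, 0), "threshold")
  expect_error(filter_identity(h, 101), "threshold")
})

test_that("locus assembly strips gaps, drops exclusions and empty sequences", {
  h <- rbind(make_hit(species = "a", s_seq = "AC-GTACGTACG"),
             make_hit(species = "b"),
             make_hit(species = "walrus"))
  lt <- assemble_locus("P1", h, gene = "GENE1", exclude = "walrus")
  expect_equal(nrow(lt), 2L)
  expect_equal(lt$sequence[lt$species == "a"], "ACGTACGTACG")
  expect_equal(lt$match_len[lt$species == "a"], 11L)
  expect_false(any(grepl("-", lt$sequence)))
  expect_equal(attr(lt, "gene"), "GENE1")

  h2 <- rbind(make_hit(species = "a"), make_hit(species = "gappy", s_seq = "------------"))
  expect_warning(lt2 <- assemble_locus("P1", h2), "all-gap")
  expect_equal(lt2$species, "a")
})

test_that("group mean match lengths equal a flat recount", {
  set.seed(21)
  loci <- lapply(1:6, function(i) {
    h <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(sp) {
      len <- sample(8:12, 1)
      make_hit(species = sp, aln_len = len,
               s_seq = paste(rep("A", len), collapse = ""))
    }))
    assemble_locus("P1", h)
  })
  part <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  got <- match_length_summary(loci, part)
  flat <- do.call(rbind, lapply(loci, as.data.frame))
  expect_equal(got[["g1"]], mean(flat$match_len[flat$species %in% c("a", "b")]))
  expect_equal(got[["g2"]], mean(flat$match_len[flat$species %in% c("c", "d")]))
  # single entry and empty group
  one <- list(assemble_locus("P1", make_hit(species = "a", aln_len = 12L)))
  expect_equal(match_length_summary(one, c(a = "g1", zz = "g2")),
               c(g1 = 12, g2 = NA))
})
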