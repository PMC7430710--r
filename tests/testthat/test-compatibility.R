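test_that("locus containment flags follow presence/absence of alleles", {
  expect_equal(locus_flags(c(100, 102), c(100, 102))[1:2],
               list(foal_in_mare = TRUE, mare_in_foal = TRUE))
  expect_equal(locus_flags(c(100, 102), c(100, 100))[1:2],
               list(foal_in_mare = TRUE, mare_in_foal = FALSE))
  expect_equal(locus_flags(c(100, 102), c(100, 104))[1:2],
               list(foal_in_mare = FALSE, mare_in_foal = FALSE))
  # homozygote notation is a multiset; containment uses distinct alleles
  expect_true(locus_flags(c(100, 100), c(100, 100))$mare_in_foal)
  fl <- locus_flags(NULL, c(100, 100))
  expect_false(fl$testable)
})

test_that("class aggregation maps flag patterns to MC/FC/MFC/NC", {
  panel <- toy_panel(3, classes = rep("I", 3))
  # flags (T,T),(T,F),(T,T) -> MC
  tab <- make_table(list(
    mare = list(c(1, 2), c(1, 2), c(3, 4)),
    foal = list(c(1, 2), c(1, 1), c(3, 4))
  ), panel)
  expect_equal(as.character(classify_pair(tab, "mare", "foal", "I")$category),
               "MC")
  # flags (T,F),(F,T),(T,T) -> NC
  tab2 <- make_table(list(
    mare = list(c(1, 2), c(5, 5), c(3, 4)),
    foal = list(c(1, 1), c(5, 6), c(3, 4))
  ), panel)
  expect_equal(as.character(classify_pair(tab2, "mare", "foal", "I")$category),
               "NC")
  # all loci identical -> MFC
  tab3 <- make_table(list(
    mare = list(c(1, 2), c(5, 6), c(3, 4)),
    foal = list(c(1, 2), c(5, 6), c(3, 4))
  ), panel)
  expect_equal(as.character(classify_pair(tab3, "mare", "foal", "I")$category),
               "MFC")
})

test_that("classifier equals brute-force containment oracle on all
           <=3-locus, <=3-allele genotype combinations", {
  alleles <- c(1L, 2L, 3L)
  genos <- list()
  for (a in alleles) for (b in alleles) if (a <= b) {
    genos[[length(genos) + 1]] <- c(a, b)
  }
  for (n_loci in 1:3) {
    panel <- toy_panel(n_loci, classes = rep("I", n_loci))
    combos <- expand.grid(rep(list(seq_along(genos)), 2 * n_loci))
    # cap the 3-locus explosion by a deterministic stride over all rows
    step <- max(1L, nrow(combos) %/% 2000L)
    for (row in seq(1, nrow(combos), by = step)) {
      pick <- as.integer(combos[row, ])
      mare <- lapply(pick[seq_len(n_loci)], function(i) genos[[i]])
      foal <- lapply(pick[n_loci + seq_len(n_loci)], function(i) genos[[i]])
      tab <- make_table(list(mare = mare, foal = foal), panel)
      got <- as.character(classify_pair(tab, "mare", "foal", "I")$category)
      expect_equal(got, oracle_category(mare, foal))
    }
  }
})

test_that("classification ignores locus order and allele order", {
  panel <- toy_panel(3, classes = rep("II", 3))
  mare <- list(c(2, 1), c(5, 6), c(8, 8))
  foal <- list(c(1, 1), c(6, 5), c(8, 8))
  tab <- make_table(list(mare = mare, foal = foal), panel)
  base <- as.character(classify_pair(tab, "mare", "foal", "II")$category)
  perm <- c(3, 1, 2)
  panel_p <- locus_panel(panel$name[perm], panel$mhc_class[perm],
                         panel$size_min[perm], panel$size_max[perm],
                         panel$multiplex[perm])
  tab_p <- make_table(list(mare = mare[perm], foal = foal[perm]), panel_p)
  expect_equal(as.character(classify_pair(tab_p, "mare", "foal",
                                          "II")$category), base)
})

test_that("missing loci are skipped by default and fatal in strict mode", {
  panel <- toy_panel(2, classes = rep("I", 2))
  tab <- make_table(list(
    mare = list(c(1, 2), NULL),
    foal = list(c(1, 2), c(3, 4))
  ), panel)
  call <- classify_pair(tab, "mare", "foal", "I")
  expect_equal(as.character(call$category), "MFC")
  expect_equal(call$loci_used, 1L)
  expect_error(classify_pair(tab, "mare", "foal", "I",
                             missing_policy = "strict"), "undetermined")
  tab2 <- make_table(list(mare = list(NULL, NULL),
                          foal = list(c(1, 1), c(2, 2))), panel)
  expect_error(classify_pair(tab2, "mare", "foal", "I"), "zero testable")
})

test_that("true parent-offspring pairs share an allele at every locus", {
  cfg <- simulation_config(n_pairs = 50, null_allele_freq = c(COR110 = 0),
                           seed = 21)
  st <- simulate_study(cfg)
  for (i in seq_len(50)) {
    for (loc in st$genotypes$loci) {
      m <- genotype_call(st$genotypes, st$pairs$mare_id[i], loc)
      f <- genotype_call(st$genotypes, st$pairs$foal_id[i], loc)
      expect_gt(length(intersect(m, f)), 0)
    }
  }
})

test_that("tabulation is pure bookkeeping: counts equal label counts and
           rows sum to group size", {
  st <- simulate_study(simulation_config(seed = 13))
  calls <- classify_pairs(st$genotypes, st$pairs)
  counts <- tabulate_compatibility(calls)
  for (g in c("RFM", "control")) {
    for (cl in c("I", "II")) {
      row <- counts[counts$group == g & counts$mhc_class == cl, ]
      expect_equal(sum(row$n), row$group_n[1])
      in_group <- if (g == "RFM") calls$rfm else !calls$rfm
      for (cat in c("MC", "FC", "MFC", "NC")) {
        expect_equal(row$n[row$category == cat],
                     sum(calls$category == cat & calls$mhc_class == cl &
                           in_group))
      }
    }
  }
  expect_equal(sum(counts$group_n[counts$mhc_class == "I" &
                                    counts$category == "MC"]), 43)
})

test_that("a single all-identical pair lands in MFC for both classes", {
  panel <- default_mhc_panel()
  genos <- lapply(panel$size_min, function(m) c(m, m + 2L))
  tab <- make_table(list(m1 = genos, f1 = genos), panel)
  pairs <- data.frame(mare_id = "m1", foal_id = "f1", rfm = TRUE)
  counts <- tabulate_compatibility(classify_pairs(tab, pairs))
  mfc <- counts[counts$group == "RFM" & counts$category == "MFC", ]
  expect_equal(mfc$n, c(1L, 1L))
  expect_equal(sum(counts$n), 2L)
})
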