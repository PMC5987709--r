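test_that("channel normalization equalizes medians then applies concentrations", {
  # medians 10/20/40 across channels, equal concentrations
  tab <- toy_peptide_table(list(
    A = c(5, 10, 20, 5, 10, 20),
    B = c(10, 20, 40, 10, 20, 40),
    C = c(20, 40, 80, 20, 40, 80)))
  norm <- normalize_channels(tab, toy_meta())
  meds <- vapply(paste0("c", 1:6), function(ch) median(norm[[ch]]), numeric(1))
  expect_equal(unname(diff(range(meds))), 0, tolerance = 1e-12)

  # equal medians, concentration 2 for the TNFa channels -> exactly 2x
  tab2 <- toy_peptide_table(list(A = rep(c(1, 5, 9), 2), B = rep(5, 6)))
  norm2 <- normalize_channels(tab2, toy_meta(conc = c(1, 1, 1, 2, 2, 2)))
  expect_equal(norm2$c4, 2 * tab2$c4, tolerance = 1e-12)
  expect_equal(norm2$c1, tab2$c1, tolerance = 1e-12)

  # idempotence
  again <- normalize_channels(norm2, toy_meta(conc = c(1, 1, 1, 2, 2, 2)))
  expect_equal(again, norm2, tolerance = 1e-12)

  # all-zero channel is an error naming the channel
  tab3 <- toy_peptide_table(list(A = c(1, 1, 1, 1, 1, 0)))
  expect_error(normalize_channels(tab3, toy_meta()), "c6")
})

test_that("Top3 follows its definition and basic monotonicity", {
  tab <- rbind(
    toy_peptide_table(list(P5 = rep(1, 6))),
    transform(toy_peptide_table(list(P5 = rep(2, 6))), peptide_id = "P5_2"),
    transform(toy_peptide_table(list(P5 = rep(3, 6))), peptide_id = "P5_3"),
    transform(toy_peptide_table(list(P5 = rep(4, 6))), peptide_id = "P5_4"),
    transform(toy_peptide_table(list(P5 = rep(5, 6))), peptide_id = "P5_5"),
    toy_peptide_table(list(P1 = rep(7, 6))))
  ab <- top3(tab)
  expect_equal(unname(ab["P5", ]), rep(4, 6))  # mean of {3,4,5}
  expect_equal(unname(ab["P1", ]), rep(7, 6))  # single peptide rule

  # permutation invariance in peptide order
  ab2 <- top3(tab[sample(nrow(tab)), ])
  expect_equal(ab2[rownames(ab), ], ab)

  # monotone in a single peptide intensity
  tab_up <- tab
  tab_up$c1[tab_up$peptide_id == "P5_5"] <- 50
  expect_gt(top3(tab_up)["P5", "c1"], ab["P5", "c1"])

  # three peptides {10,20,30} -> 20
  t3 <- do.call(rbind, lapply(1:3, function(k) {
    transform(toy_peptide_table(list(Q = rep(10 * k, 6))),
              peptide_id = sprintf("Q_%d", k))
  }))
  expect_equal(unname(top3(t3)["Q", ]), rep(20, 6))
})

test_that("noise-free spiked data is an exact fixed point of the pipeline", {
  # spike a far-above-median protein 2-fold; cv = 0, unit concentrations
  fc <- rep(0, 60); fc[1] <- 1
  sim <- simulate_peptide_table(
    n_proteins = 60, peptides_per_protein = 5, log2_fold_changes = fc,
    peptide_cv = 0, base_abundance = c(1e9, rep(1e6, 59)), seed = 7)
  norm <- normalize_channels(sim$table, sim$meta)
  q <- ratios_and_significance(top3(norm), norm, sim$meta,
                               treated = "TNFa", reference = "ss")
  expect_equal(q$ratio[q$protein_id == "P00001"], 2, tolerance = 1e-12)
  expect_equal(q$ratio[q$protein_id != "P00001"], rep(1, 59),
               tolerance = 1e-12)
  # all fold changes 1 in noise-free data -> nothing significant
  expect_equal(sum(q$significant[q$protein_id != "P00001"]), 0)
})

test_that("spiked proteins are recovered and flagged significant", {
  fc <- rep(0, 200)
  fc[1:10] <- 2  # 4-fold up
  sim <- simulate_peptide_table(n_proteins = 200, peptides_per_protein = 6,
                                log2_fold_changes = fc, peptide_cv = 0.1,
                                seed = 21)
  norm <- normalize_channels(sim$table, sim$meta)
  q <- ratios_and_significance(top3(norm), norm, sim$meta,
                               treated = "TNFa", reference = "ss")
  spiked <- q[match(sprintf("P%05d", 1:10), q$protein_id), ]
  expect_true(all(spiked$significant))
  expect_true(all(abs(log2(spiked$ratio) - 2) < 0.5))
  # count under "ratio >= 1.5 and significant" matches the design
  n_called <- sum(q$ratio >= 1.5 & q$significant, na.rm = TRUE)
  expect_true(abs(n_called - 10) <= 3)
})

test_that("log2 ratio recovery: |bias| < 0.05 and MAE < 0.15", {
  fc <- rep(0, 1000)
  fc[1:100] <- rep(c(1, -1), 50)
  sim <- simulate_peptide_table(n_proteins = 1000, log2_fold_changes = fc,
                                peptide_cv = 0.2, seed = 13)
  norm <- normalize_channels(sim$table, sim$meta)
  q <- ratios_and_significance(top3(norm), norm, sim$meta,
                               treated = "TNFa", reference = "ss")
  est <- log2(q$ratio)[match(sim$truth$protein_id, q$protein_id)]
  err <- est - sim$truth$log2_fold_change
  expect_lt(abs(mean(err, na.rm = TRUE)), 0.05)
  expect_lt(mean(abs(err), na.rm = TRUE), 0.15)
})

test_that("ratio density reports the histogram and overall fold change", {
  sim <- simulate_peptide_table(n_proteins = 50, peptides_per_protein = 4,
                                peptide_cv = 0, seed = 3)
  norm <- normalize_channels(sim$table, sim$meta)
  q <- ratios_and_significance(top3(norm), norm, sim$meta,
                               treated = "TNFa", reference = "ss")
  dens <- ratio_density(q)
  # dataset against itself: overall fold change exactly 1, all mass at 0
  expect_equal(dens$overall_fold_change, 1, tolerance = 1e-12)
  expect_equal(sum(dens$histogram$fraction), 1, tolerance = 1e-12)
  expect_equal(dens$histogram$count[dens$histogram$bin_lo <= 0 &
                                    dens$histogram$bin_hi >= 0], 50)

  # symmetric +-1 log2 spikes at equal base abundance: the log-ratio
  # distribution is centred on 0 (geometric "overall" of 1), while the
  # arithmetic-sum overall fold change tends to mean(2, 0.5) = 1.25
  fc <- rep(c(1, -1), 25)
  sim2 <- simulate_peptide_table(n_proteins = 50, peptides_per_protein = 4,
                                 log2_fold_changes = fc, peptide_cv = 0,
                                 base_abundance = 1e6, seed = 4)
  norm2 <- normalize_channels(sim2$table, sim2$meta)
  q2 <- ratios_and_significance(top3(norm2), norm2, sim2$meta,
                                treated = "TNFa", reference = "ss")
  d2 <- ratio_density(q2)
  expect_lt(abs(mean(q2$log10_ratio, na.rm = TRUE)), 0.05)
  expect_lt(abs(d2$overall_fold_change - 1.25), 0.15)
})

test_that("heat-map values are log10 ratios to the ss mean", {
  ab <- rbind(A = c(2, 2, 2, 20, 20, 20),
              B = c(5, 5, 5, 5, 5, 5))
  colnames(ab) <- paste0("c", 1:6)
  hm <- heatmap_matrix(ab, toy_meta(), reference = "ss")
  expect_equal(unname(hm["A", 1:3]), rep(0, 3))   # ss columns all 0
  expect_equal(unname(hm["A", 4:6]), rep(1, 3))   # 10x the ss mean
  expect_equal(mean(hm["B", 1:3]), 0)
})

test_that("cluster enrichment follows its defining ratio", {
  ab <- rbind(A = rep(1, 6), B = rep(3, 6), C = rep(8, 6))
  colnames(ab) <- paste0("c", 1:6)
  meta <- toy_meta()
  # cluster of everything -> exactly 1
  all_cl <- cluster_enrichment(ab, list(all = c("A", "B", "C")), meta)
  expect_equal(all_cl$enrichment, rep(1, 2))
  # hand computation: {C} vs mean {1,3,8} = 8/4
  one <- cluster_enrichment(ab, list(big = "C"), meta)
  expect_equal(one$enrichment, rep(2, 2))
  # global rescaling invariance
  sc <- cluster_enrichment(ab * 37.5, list(big = "C"), meta)
  expect_equal(sc$enrichment, one$enrichment, tolerance = 1e-12)
  # unmatched ids reported; fully unmatched cluster errors with its name
  um <- cluster_enrichment(ab, list(big = c("C", "ZZZ")), meta)
  expect_equal(attr(um, "unmatched")$big, "ZZZ")
  expect_error(cluster_enrichment(ab, list(ghost = "ZZZ"), meta), "ghost")
})
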