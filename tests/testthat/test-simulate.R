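test_that("infection-matrix generator is seeded and class-faithful", {
  m1 <- simulate_infection_matrix(n_phages = 10, n_hosts = 30, seed = 5)
  m2 <- simulate_infection_matrix(n_phages = 10, n_hosts = 30, seed = 5)
  expect_identical(m1$matrix$values, m2$matrix$values)
  expect_identical(m1$matrix$states, m2$matrix$states)
  m3 <- simulate_infection_matrix(n_phages = 10, n_hosts = 30, seed = 6)
  expect_false(identical(m1$matrix$values, m3$matrix$values))

  # resistant hosts receive no positive entries
  res_hosts <- names(m1$truth$class)[m1$truth$class == "resistant"]
  expect_true(all(is.na(m1$matrix$values[, res_hosts])))

  # all-generalist, noiseless, fully susceptible: uniform titers, PDI 0
  mg <- simulate_infection_matrix(
    n_phages = 6, n_hosts = 12, frac_specialists = 0,
    class_mix = c(resistant = 0, slightly_susceptible = 0,
                  susceptible = 1),
    noise_sd = 0, seed = 2)
  expect_true(all(compute_pdi(mg$matrix)$pdi == 0))

  # a specialist's PDI equals the closed-form value of its row
  ms <- simulate_infection_matrix(n_phages = 10, n_hosts = 10,
                                  frac_specialists = 0.1, noise_sd = 0,
                                  seed = 3)
  spec_id <- names(ms$truth$archetype)[ms$truth$archetype == "specialist"]
  pdi <- compute_pdi(ms$matrix)
  row <- ms$matrix$values[spec_id[1], ]
  expect_equal(pdi$pdi[pdi$entity_id == spec_id[1]], oracle_pdi_row(row))

  expect_error(simulate_infection_matrix(
    n_hosts = 5, class_mix = c(resistant = 0.99,
                               slightly_susceptible = 0.005,
                               susceptible = 0.005)), "degenerate")
})

test_that("scoring the simulated matrix recovers the true host classes", {
  acc <- vapply(1:20, function(s) {
    m <- simulate_infection_matrix(n_phages = 18, n_hosts = 60,
                                   noise_sd = 0.3, seed = s)
    cl <- classify_hosts(susceptibility_scores(m$matrix))
    mean(as.character(cl$cls) == m$truth$class[cl$host_id])
  }, 0)
  expect_gte(mean(acc), 0.95)
})

test_that("genome generator truth: families, Dollo script and determinism", {
  # zero substitution rate, no events: families identical within, BBH = truth
  sim0 <- simulate_phage_genomes(n_taxa = 5, n_core = 6, n_accessory = 3,
                                 subst_rate = 0, recomb_events = 0,
                                 seed = 9)
  for (f in names(sim0$alignments))
    expect_equal(length(unique(sim0$alignments[[f]])), 1L)
  hits <- all_vs_all_similarity(sim0$proteomes, engine = "pairwise")
  gr <- bbh_groups(bbh_edges(hits), sim0$proteomes)
  tab <- table(gr$membership$group_id,
               sim0$truth$family_of_gene[gr$membership$gene_id])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  # determinism
  simA <- simulate_phage_genomes(n_taxa = 5, n_core = 5, n_accessory = 2,
                                 subst_rate = 0.02, recomb_events = 2,
                                 seed = 4)
  simB <- simulate_phage_genomes(n_taxa = 5, n_core = 5, n_accessory = 2,
                                 subst_rate = 0.02, recomb_events = 2,
                                 seed = 4)
  expect_identical(simA$alignments, simB$alignments)
  expect_identical(simA$events$start, simB$events$start)

  # Dollo on the emitted presence/absence recovers the scripted history
  for (seed in 1:5) {
    sim <- simulate_phage_genomes(n_taxa = 7, n_core = 4, n_accessory = 6,
                                  subst_rate = 0.01, recomb_events = 0,
                                  seed = seed)
    dol <- dollo_gain_loss(sim$truth$presence, sim$tree)
    tg <- merge(dol$per_family, sim$truth$gains, by = "family")
    expect_equal(tg$gain_branch.x, tg$gain_branch.y)
    lt <- table(sim$truth$losses$loss_branch)
    pb <- dol$per_branch
    expect_equal(pb$losses[match(names(lt), pb$branch)],
                 unname(as.integer(lt)))
    expect_equal(sum(pb$losses), nrow(sim$truth$losses))
  }
})

test_that("recombination injections lower the target family's identity", {
  # paired comparison across seeds: the injected hotspot family is more
  # divergent than the non-injected families evolved at the same rate
  delta <- vapply(1:100, function(s) {
    sim <- simulate_phage_genomes(n_taxa = 6, n_core = 6, n_accessory = 0,
                                  hotspot_positions = list(hs = 3L),
                                  subst_rate = 0.02, recomb_events = 1,
                                  seed = s)
    idf <- vapply(names(sim$alignments), function(f)
      family_alignment_stats(sim$alignments[[f]],
                             family_id = f)$mean_pairwise_identity, 0)
    target <- sim$events$family_id[1]
    idf[[target]] - mean(idf[setdiff(names(idf), target)])
  }, 0)
  expect_lt(mean(delta), 0)
  expect_lt(stats::quantile(delta, 0.8), 0)

  # events restricted to the hotspot range
  expect_error(simulate_phage_genomes(
    n_taxa = 5, n_core = 10, n_accessory = 0,
    hotspot_positions = list(hs = 4:5),
    recomb_events = data.frame(family_idx = 9L, donor = "G01",
                               recipient = "G02"),
    seed = 1), "hotspot")
})

test_that("emitted artifacts re-parse through the package readers cleanly", {
  dir <- withr::local_tempdir()
  expect_no_warning({
    sim <- simulate_phage_genomes(n_taxa = 5, n_core = 6, n_accessory = 3,
                                  subst_rate = 0.02, recomb_events = 2,
                                  seed = 13, out_dir = dir)
    pr <- read_annotated_genomes(sim$files$annotations, sim$files$proteins)
    ev <- parse_recombination_gff(sim$files$recomb_gff)
    pd <- patristic_distance_matrix(sim$files$tree)
  })
  expect_identical(lapply(pr[names(sim$proteomes)], as.data.frame),
                   lapply(sim$proteomes, as.data.frame))
  expect_identical(ev$start, sim$events$start)
  expect_identical(ev$end, sim$events$end)
  expect_setequal(rownames(pd), names(sim$proteomes))
  for (p in sim$files$alignments) {
    aln <- Biostrings::readDNAStringSet(p)
    expect_gt(length(aln), 0)
  }
  # the recombination events map onto the emitted coordinate system
  mapped <- map_events_to_genes(ev, sim$coord_map)
  expect_equal(sum(mapped$per_family$recomb_event_count > 0) > 0,
               nrow(ev) > 0)
})
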