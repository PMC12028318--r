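tiny_proteome <- function(genome_id, proteins, starts = NULL) {
  n <- length(proteins)
  if (is.null(starts)) starts <- seq(0, by = 1000, length.out = n)
  proteome(genome_id,
           gene_id = names(proteins),
           strand = rep("+", n),
           start = starts, end = starts + 3 * nchar(proteins),
           protein = unname(proteins))
}

test_that("gene calls are ordered by start and validated", {
  p <- proteome("g", gene_id = c("x", "y", "z"), strand = c("+", "+", "-"),
                start = c(900, 10, 500), end = c(990, 100, 590),
                protein = c("MAAA", "MCCC", "MDDD"))
  expect_equal(p$gene_id, c("y", "z", "x"))
  expect_equal(p$rank, 0:2)
  expect_error(proteome("g", "x", "+", 100, 50, "MA"), "end <= start")
  expect_error(proteome("g", c("x", "x"), c("+", "+"), c(0, 10), c(5, 20),
                        c("MA", "MC")), "duplicate")
})

test_that("GFF3+FASTA and GenBank routes produce identical proteomes", {
  prots <- c(gA_1 = "MKLVINSLRTT", gA_2 = "MNPQRSTVWYAACD",
             gA_3 = "MGGHHIKLMNP")
  p <- tiny_proteome("gA", prots)
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "gA.gff3"); faa <- file.path(dir, "gA.faa")
  write_proteome(p, gff, faa)
  p_gff <- read_annotated_genome(gff = gff, proteins = faa, genome_id = "gA")
  expect_identical(as.data.frame(p_gff), as.data.frame(p))

  gbk <- file.path(dir, "gA.gbk")
  write_fake_genbank(gbk, "gA", p)
  p_gbk <- read_annotated_genome(genbank = gbk, genome_id = "gA")
  expect_identical(as.data.frame(p_gbk), as.data.frame(p))

  # a CDS without protein sequence is a named error
  aa <- Biostrings::readAAStringSet(faa)
  Biostrings::writeXStringSet(aa[-2], faa)
  expect_error(read_annotated_genome(gff = gff, proteins = faa), "gA_2")
})

test_that("pairwise local alignment reports identity and coverage correctly", {
  a <- "ACDEFGHIKLACDEFGHIKL"
  b <- sub("^(.{5}).", "\\1W", a)       # one substitution at position 6
  ps <- list(tiny_proteome("g1", c(p1 = a)),
             tiny_proteome("g2", c(p2 = b), starts = 0),
             tiny_proteome("g3", c(p3 = a), starts = 0))
  hits <- all_vs_all_similarity(ps, engine = "pairwise")
  h_ident <- hits[hits$query_id == "p1" & hits$target_id == "p3", ]
  expect_equal(h_ident$identity, 100)
  expect_equal(h_ident$coverage_shortest, 100)
  h_sub <- hits[hits$query_id == "p1" & hits$target_id == "p2", ]
  expect_equal(h_sub$identity, 95)      # 19/20 aligned columns identical
  expect_equal(h_sub$coverage_shortest, 100)
  # hit table carries both directions with equal identity
  h_rev <- hits[hits$query_id == "p2" & hits$target_id == "p1", ]
  expect_equal(h_rev$identity, h_sub$identity)
})

test_that("unrelated random proteins fall below the BBH cutoffs", {
  set.seed(33)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  rnd <- function() paste(sample(aa, 50, replace = TRUE), collapse = "")
  ps <- list(tiny_proteome("g1", c(r1 = rnd())),
             tiny_proteome("g2", c(r2 = rnd())))
  hits <- all_vs_all_similarity(ps, engine = "pairwise")
  edges <- bbh_edges(hits)
  expect_equal(nrow(edges), 0L)
})

test_that("BBH edges demand mutual best hits above both cutoffs", {
  mk_hit <- function(q, t, qg, tg, id, cov, sc)
    data.frame(query_id = q, target_id = t, query_genome = qg,
               target_genome = tg, identity = id, coverage_shortest = cov,
               score = sc, stringsAsFactors = FALSE)
  # mutual best pair passes
  h <- rbind(mk_hit("a1", "b1", "A", "B", 95, 100, 500),
             mk_hit("b1", "a1", "B", "A", 95, 100, 500))
  expect_equal(nrow(bbh_edges(h)), 1L)
  # a's best is b1 but b1's best is a2: no edge for (a1, b1)
  h2 <- rbind(mk_hit("a1", "b1", "A", "B", 90, 100, 400),
              mk_hit("b1", "a1", "B", "A", 90, 100, 400),
              mk_hit("b1", "a2", "B", "A", 95, 100, 500),
              mk_hit("a2", "b1", "A", "B", 95, 100, 500))
  e2 <- bbh_edges(h2)
  expect_equal(nrow(e2), 1L)
  expect_setequal(c(e2$gene_a, e2$gene_b), c("a2", "b1"))
  # mutual best at 19% identity is filtered by the >20% cutoff
  h3 <- rbind(mk_hit("a1", "b1", "A", "B", 19, 100, 100),
              mk_hit("b1", "a1", "B", "A", 19, 100, 100))
  expect_equal(nrow(bbh_edges(h3)), 0L)
  expect_equal(nrow(bbh_edges(h3, id_cutoff = 15)), 1L)
  # coverage cutoff is strict too
  h4 <- rbind(mk_hit("a1", "b1", "A", "B", 90, 50, 100),
              mk_hit("b1", "a1", "B", "A", 90, 50, 100))
  expect_equal(nrow(bbh_edges(h4)), 0L)
  # score ties broken by identity then lexicographic target id
  h5 <- rbind(mk_hit("a1", "b2", "A", "B", 90, 100, 500),
              mk_hit("a1", "b1", "A", "B", 90, 100, 500),
              mk_hit("b1", "a1", "B", "A", 90, 100, 500),
              mk_hit("b2", "a1", "B", "A", 90, 100, 500))
  e5 <- bbh_edges(h5)
  expect_equal(nrow(e5), 1L)
  expect_setequal(c(e5$gene_a, e5$gene_b), c("a1", "b1"))
})

test_that("BBH groups partition all genes; components match reachability", {
  ps <- list(tiny_proteome("g1", c(a1 = "MKL", a2 = "MNP")),
             tiny_proteome("g2", c(b1 = "MKL", b2 = "MNP")),
             tiny_proteome("g3", c(c1 = "MKL")))
  # no edges: every gene a singleton
  g0 <- bbh_groups(data.frame(gene_a = character(0),
                              gene_b = character(0)), ps)
  expect_equal(nrow(g0$groups), 5L)
  expect_true(all(g0$groups$n_members == 1))
  # chain a1-b1, b1-c1 -> one family of 3
  ed <- data.frame(gene_a = c("a1", "b1"), gene_b = c("b1", "c1"))
  g1 <- bbh_groups(ed, ps)
  expect_equal(sort(g1$groups$n_members, decreasing = TRUE)[1], 3L)
  expect_equal(sum(g1$groups$n_members), 5L)
  fam3 <- g1$groups$group_id[g1$groups$n_members == 3]
  expect_true(g1$groups$is_core[g1$groups$group_id == fam3])

  # random edge sets: components equal brute-force reachability
  set.seed(12)
  genes <- sprintf("x%02d", 1:12)
  psr <- list(tiny_proteome("G", setNames(rep("MKL", 12), genes)))
  for (rep in 1:10) {
    k <- sample(0:10, 1)
    ed <- unique(data.frame(
      gene_a = sample(genes, k, replace = TRUE),
      gene_b = sample(genes, k, replace = TRUE)))
    ed <- ed[ed$gene_a != ed$gene_b, , drop = FALSE]
    gr <- bbh_groups(ed, psr)
    oc <- oracle_components(genes, data.frame(a = ed$gene_a, b = ed$gene_b))
    got <- setNames(gr$membership$group_id, gr$membership$gene_id)[genes]
    expect_equal(length(unique(got)), length(unique(oc)))
    expect_true(all(tapply(oc, got, function(x) length(unique(x))) == 1))
  }
})

test_that("persistence spectrum fractions sum to one and reflect the truth", {
  sim <- simulate_phage_genomes(n_taxa = 6, n_core = 6, n_accessory = 8,
                                subst_rate = 0, recomb_events = 0, seed = 4)
  hits <- all_vs_all_similarity(sim$proteomes, engine = "pairwise")
  gr <- bbh_groups(bbh_edges(hits), sim$proteomes)
  expect_equal(sum(gr$spectrum), 1)
  expect_equal(sum(gr$groups$is_core),
               sum(rowSums(sim$truth$presence) == 6))
})

test_that("adjacency graph weights count genome-supported neighborhoods", {
  ps <- list(tiny_proteome("g1", c(a1 = "MKL", b1 = "MNP", c1 = "MQR")),
             tiny_proteome("g2", c(a2 = "MKL", c2 = "MQR", b2 = "MNP")))
  ed <- data.frame(gene_a = c("a1", "b1", "c1"),
                   gene_b = c("a2", "b2", "c2"))
  gr <- bbh_groups(ed, ps)
  fam <- setNames(gr$membership$group_id, gr$membership$gene_id)
  pg <- pangenome_adjacency_graph(gr, ps)
  w <- function(x, y) {
    i <- (pg$edges$group_a == min(fam[x], fam[y])) &
      (pg$edges$group_b == max(fam[x], fam[y]))
    if (any(i)) pg$edges$weight[i] else 0L
  }
  # genomes [a,b,c] and [a,c,b]: a-b once, b-c twice, a-c once
  expect_equal(w("a1", "b1"), 1L)
  expect_equal(w("b1", "c1"), 2L)
  expect_equal(w("a1", "c1"), 1L)
  expect_equal(sum(pg$edges$weight), sum(sapply(ps, nrow) - 1))

  # single two-gene genome
  ps1 <- ps[1]
  gr1 <- bbh_groups(data.frame(gene_a = character(0),
                               gene_b = character(0)), ps1)
  pg1 <- pangenome_adjacency_graph(gr1, ps1)
  expect_equal(nrow(pg1$edges), 2L)
  expect_equal(sum(pg1$edges$weight), 2L)

  # circular adds the wrap-around adjacency
  pgc <- pangenome_adjacency_graph(gr1, ps1, circular = TRUE)
  expect_equal(sum(pgc$edges$weight), 3L)
})

test_that("weight conservation holds on simulated genome sets", {
  for (seed in 1:3) {
    sim <- simulate_phage_genomes(n_taxa = 5, n_core = 8, n_accessory = 5,
                                  subst_rate = 0.02, recomb_events = 0,
                                  seed = seed)
    hits <- all_vs_all_similarity(sim$proteomes, engine = "pairwise")
    gr <- bbh_groups(bbh_edges(hits), sim$proteomes)
    pg <- pangenome_adjacency_graph(gr, sim$proteomes)
    expect_equal(sum(pg$edges$weight),
                 sum(vapply(sim$proteomes, nrow, 0L) - 1L))
  }
})

test_that("synteny links join shared families of adjacent genomes only", {
  ps <- list(tiny_proteome("g1", c(a1 = "MKL", b1 = "MNP")),
             tiny_proteome("g2", c(a2 = "MKL", b2 = "MNP")),
             tiny_proteome("g3", c(a3 = "MKL")))
  ed <- data.frame(gene_a = c("a1", "a2", "b1"),
                   gene_b = c("a2", "a3", "b2"))
  gr <- bbh_groups(ed, ps)
  links <- synteny_links(gr, ps, c("g1", "g2", "g3"))
  # pairs (g1,g2): 2 links; (g2,g3): 1 link (b absent from g3); none (g1,g3)
  expect_equal(sum(links$genome_a == "g1" & links$genome_b == "g2"), 2L)
  expect_equal(sum(links$genome_a == "g2" & links$genome_b == "g3"), 1L)
  expect_equal(nrow(links), 3L)
  expect_error(synteny_links(gr, ps, c("g1", "gX")), "gX")
})

test_that("ICTV-style rank clustering is single-linkage and nested", {
  ids <- c("A", "B", "C")
  sim <- matrix(c(100, 96, 80,
                  96, 100, 96,
                  80, 96, 100), 3, 3, dimnames = list(ids, ids))
  cl <- intergenomic_similarity_classify(sim)
  # chained 96% links merge all three at species level by single linkage
  expect_equal(length(unique(cl$species)), 1L)
  expect_equal(length(unique(cl$genus)), 1L)
  expect_equal(length(unique(cl$family)), 1L)

  sim2 <- matrix(c(100, 60, 60, 100), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  cl2 <- intergenomic_similarity_classify(sim2)
  expect_equal(length(unique(cl2$family)), 1L)
  expect_equal(length(unique(cl2$genus)), 2L)
  expect_equal(length(unique(cl2$species)), 2L)

  # nestedness on random symmetric matrices
  set.seed(9)
  for (rep in 1:5) {
    n <- 8
    m <- matrix(runif(n * n, 30, 100), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 100
    dimnames(m) <- list(letters[1:n], letters[1:n])
    cl <- intergenomic_similarity_classify(m)
    agg <- function(fine, coarse)
      all(tapply(cl[[coarse]], cl[[fine]], function(x)
        length(unique(x))) == 1)
    expect_true(agg("species", "genus"))
    expect_true(agg("genus", "family"))
  }

  bad <- sim; bad[1, 2] <- 50
  expect_error(intergenomic_similarity_classify(bad), "asymmetric")
})

test_that("BLAST and built-in engines recover the same families", {
  sim <- simulate_phage_genomes(n_taxa = 5, n_core = 10, n_accessory = 4,
                                subst_rate = 0.02, recomb_events = 2,
                                seed = 11)
  fam_of <- sim$truth$family_of_gene
  for (eng in c("pairwise", "blast")) {
    hits <- all_vs_all_similarity(sim$proteomes, engine = eng)
    gr <- bbh_groups(bbh_edges(hits), sim$proteomes)
    tab <- table(gr$membership$group_id, fam_of[gr$membership$gene_id])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1),
                label = paste("exact family recovery with engine", eng))
  }
})
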