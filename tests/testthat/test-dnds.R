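rep_codon <- function(codon, n) paste(rep(codon, n), collapse = "")

test_that("degenerate alignments produce flagged, not numeric, ratios", {
  # identical sequences: no differences at all
  aln <- c(a = rep_codon("GGA", 10), b = rep_codon("GGA", 10))
  d <- counting_dnds(aln)
  expect_equal(d$dN, 0)
  expect_equal(d$dS, 0)
  expect_false(d$defined)
  expect_true(is.na(d$dnds))
  # one nonsynonymous difference, no synonymous: dS = 0 guard
  a <- paste0(rep_codon("GGA", 10), "ATG")
  b <- paste0(rep_codon("GGA", 10), "ATA")   # Met -> Ile
  d2 <- counting_dnds(c(a = a, b = b))
  expect_gt(d2$dN, 0)
  expect_equal(d2$dS, 0)
  expect_false(d2$defined)
})

test_that("a single synonymous third-position change gives ratio zero", {
  a <- rep_codon("GGA", 11)
  b <- paste0(rep_codon("GGA", 10), "GGG")   # Gly -> Gly
  d <- counting_dnds(c(a = a, b = b))
  expect_equal(d$dN, 0)
  expect_gt(d$dS, 0)
  expect_true(d$defined)
  expect_equal(d$dnds, 0)
})

test_that("site counts match hand enumeration for known codons", {
  # hand-derived synonymous site fractions under the standard code:
  # TTT (Phe): only TTC of the 9 single changes is synonymous -> S = 1/3
  # ATG (Met): no synonymous change -> S = 0
  # GGG (Gly): third position fully degenerate -> S = 1
  # CGA (Arg): CGx third position (3/3) plus AGA via first position -> 4/3
  a <- paste0("TTT", "ATG", "GGG", "CGA")
  d <- counting_dnds(c(a = a, b = a))
  expect_equal(d$n_sites_S, 1 / 3 + 0 + 1 + 4 / 3)
  expect_equal(d$n_sites_N, 12 - (1 / 3 + 0 + 1 + 4 / 3))
})

test_that("pathway averaging splits two-position differences correctly", {
  # TTT -> TTA via TTA only needs pos3 (Leu, nonsyn); pair with 2 diffs:
  # TTT (F) vs CTA (L): pathways TTT-CTT(L)-CTA(L): 1 nonsyn + 1 syn;
  # TTT-TTA(L)-CTA(L): 1 nonsyn + 1 syn -> Nd = 1, Sd = 1
  a <- paste0(rep_codon("ATG", 10), "TTT")
  b <- paste0(rep_codon("ATG", 10), "CTA")
  d <- counting_dnds(c(a = a, b = b))
  expect_equal(d$pN * d$n_sites_N, 1)   # Nd = 1
  expect_equal(d$pS * d$n_sites_S, 1)   # Sd = 1
})

test_that("gap-heavy columns are trimmed and stop codons rejected", {
  # 5 sequences; one codon column gapped in 1/5 (20%) is removed at the
  # default threshold (< 20% retained)
  base <- rep_codon("GGA", 4)
  aln <- c(s1 = paste0(base, "AAA"), s2 = paste0(base, "AAA"),
           s3 = paste0(base, "AAA"), s4 = paste0(base, "AAA"),
           s5 = paste0(base, "---"))
  d <- counting_dnds(aln)
  expect_equal(d$n_codons_used, 4L)
  d2 <- counting_dnds(aln, gap_col_threshold = 25)
  expect_equal(d2$n_codons_used, 5L)

  bad <- c(a = paste0("TAA", rep_codon("GGA", 3)),
           b = paste0("TAC", rep_codon("GGA", 3)))
  expect_error(counting_dnds(bad), "stop codon in sequence a at codon 1")
})

test_that("adding a nonsynonymous difference never decreases dN", {
  set.seed(8)
  base <- rep_codon("GGA", 30)
  prev <- 0
  seqs <- c(a = base, b = base)
  for (k in 1:5) {
    # mutate codon k of b to AGA -> GGA (G) vs AGA (R): nonsynonymous
    sub <- seqs[["b"]]
    substr(sub, 3 * k - 2, 3 * k - 2) <- "A"
    seqs[["b"]] <- sub
    d <- counting_dnds(seqs)
    expect_gte(d$dN, prev)
    prev <- d$dN
  }
})

test_that("external dN/dS tables are parsed with or without header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tdnds", "f1\t0.12", "f2\t0.35"), path)
  tab <- read_dnds_table(path)
  expect_equal(tab$dnds, c(0.12, 0.35))
  writeLines(c("f1\t0.12", "f2\t0.35"), path)
  expect_equal(read_dnds_table(path)$family_id, c("f1", "f2"))
})

test_that("association report covers class test and rank correlations", {
  set.seed(10)
  n <- 40
  stats_df <- data.frame(
    family_id = sprintf("f%02d", 1:n),
    mean_pairwise_identity = c(runif(10, 70, 94), runif(30, 96, 100)),
    is_divergent = rep(c(TRUE, FALSE), c(10, 30)),
    recomb_event_count = c(rpois(10, 6), rpois(30, 0.5)),
    dnds = runif(n, 0, 0.4))
  res <- divergence_association(stats_df)
  mw <- res[res$test == "recomb_divergent_vs_not", ]
  expect_lt(mw$p.value, 0.05)
  sp <- res[res$test == "identity_vs_recomb", ]
  expect_lt(sp$estimate, 0)
  expect_true(all(res$p.adj >= res$p.value - 1e-15, na.rm = TRUE))

  # identical counts across families: class comparison p = 1
  flat <- stats_df
  flat$recomb_event_count <- 2L
  res_flat <- divergence_association(flat)
  expect_equal(res_flat$p.value[res_flat$test == "recomb_divergent_vs_not"],
               1)
  # constant dN/dS: correlation undefined and noted
  const <- stats_df
  const$dnds <- 0.2
  res_c <- divergence_association(const)
  expect_true(is.na(res_c$p.value[res_c$test == "identity_vs_dnds"]))
  expect_match(paste(attr(res_c, "note"), collapse = " "), "constant")
  # empty divergence group: warning and correlation-only report
  nd <- stats_df
  nd$is_divergent <- FALSE
  expect_warning(res_nd <- divergence_association(nd), "empty")
  expect_false("recomb_divergent_vs_not" %in% res_nd$test)

  expect_error(divergence_association(stats_df[1:4, ]), "at least 5")
})
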