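# phagetools

Quantitative analysis of broad-host-range phage collections and their
bacterial hosts.

Cross-infection assays between a panel of phages and a panel of bacterial
strains produce a titer matrix — for every phage x host pair, either a
plaque count (PFU/ml) or a categorical outcome (resistant; resistant but
impaired, i.e. adsorption without productive infection; not assessed).
Comparative genomics of the same phage collection produces annotated
proteomes, core-gene alignments, trees and recombination predictions; lab
kinetics produce adsorption and one-step growth curves. `phagetools`
implements the complete quantitative toolchain over these inputs:

* **Ecology of the infection network.** The specialization of a phage is
  scored with the Paired Difference Index on log10 titers,

  PDI = Σᵢ₌₂..N (P₁ − Pᵢ) / (N − 1),

  where P₁ is the highest log-titer score in the row and P₂…P_N the
  others (normalized convention: scores divided by P₁, so PDI ∈ [0, 1];
  0 = uniform exploitation of all hosts, 1 = maximal specialization).
  Host-wise, the susceptibility score is 1 − PDI_host, and hosts are
  classified as resistant (score 0), slightly susceptible (0 < score
  < 0.5) or susceptible (score ≥ 0.5). Phylogenetic neighborhood traits
  (mean patristic distance and trait specificity of the k = 6 closest
  strains) are compared across classes with Kruskal–Wallis and pairwise
  Mann–Whitney tests.
* **Pangenome structure.** Gene families are built as connected
  components of the best-bidirectional-hit (BBH) graph from an
  all-vs-all protein search (identity > 20%, coverage > 50% of the
  shorter protein), classified core / single-copy, and assembled into an
  adjacency-weighted pangenome graph plus synteny links. Genomes are
  placed into family/genus/species ranks by single-linkage clustering of
  an intergenomic similarity matrix at the ICTV 50/70/95% thresholds,
  and gene gain/loss histories are reconstructed by Dollo parsimony.
* **Recombination and divergence.** Recombination predictions
  (Gubbins-dialect GFF on a concatenated core-gene alignment) are mapped
  onto per-gene coordinates; per-family divergence (mean pairwise
  identity), a Nei–Gojobori-style counting dN/dS (with an importer for
  codon-model estimates), and divergence–recombination–selection
  association tests complete the picture.
* **Life-history traits.** First-order adsorption constants from
  free-phage decay, and burst size / latent period from replicated
  one-step growth curves (plateau mean over baseline mean; last pre-rise
  time plus adsorption duration).
* **Synthetic data.** Seeded generators produce a modular infection
  matrix, a genome collection evolved on a known tree (core backbone,
  accessory islands, recombination hotspots) and noisy kinetic curves —
  each with full ground truth attached, so every stage of the pipeline is
  testable end to end without any external download.

## Worked example

```r
library(phagetools)

m <- simulate_infection_matrix(n_phages = 18, n_hosts = 157,
                               noise_sd = 0.3, seed = 42)
m$matrix
#> Cross-infection titer matrix: 18 phages x 157 hosts
#>   cells: titer=1051, resistant=1590, impaired=185, not_assessed=0

pdi <- compute_pdi(m$matrix)
head(pdi, 4)
#>   entity_id       pdi n_used flag
#> 1       P01 0.9812148    157   ok
#> 2       P02 0.9812900    157   ok
#> 3       P03 0.9935897    157   ok
#> 4       P04 0.6009386    157   ok

cl <- classify_hosts(susceptibility_scores(m$matrix))
table(cl$cls)
#>            resistant slightly_susceptible          susceptible
#>                   55                   47                   55

k <- simulate_kinetics(burst = 38, latent = 35, adsorption_rate = 0.5,
                       noise_sd = 0.1, seed = 42)
one_step_growth(k$growth, adsorption_duration = k$adsorption_duration)
#> One-step growth: burst size = 35.5 particles/cell, latent period = 35 min
#>   baseline = 10.3, plateau = 367 over t = [50, 90] min
```

The three specialist phages of this simulated panel score PDI ≈ 0.99
while the fifteen generalists average ≈ 0.62; the host classes recovered
from the scored matrix match the generator's truth exactly, and the noisy
one-step curve returns the simulated burst size of 38 to within 7%.

The pangenome route follows the same pattern:

```r
sim  <- simulate_phage_genomes(n_taxa = 18, n_core = 250,
                               n_accessory = 40, subst_rate = 0.02,
                               recomb_events = 9, seed = 1)
hits <- all_vs_all_similarity(sim$proteomes, engine = "blast")
fam  <- bbh_groups(bbh_edges(hits), sim$proteomes)
fam
#> BBH gene families: 290 families over 18 genomes
#>   core (all genomes): 250; single-copy core: 250
#>   persistence spectrum: >80%: 86.2%, <20%: 9.7%, intermediate: 4.1%
graph <- pangenome_adjacency_graph(fam, sim$proteomes)
dollo <- dollo_gain_loss(sim$truth$presence, sim$tree)
```

See the methods vignette (`vignettes/phage-collection-analysis.Rmd`) for
the models, parameter choices and limitations.

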