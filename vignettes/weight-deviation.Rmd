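---
title: "Triplet weights, 2D plot sets and the weight-deviation distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet weights, 2D plot sets and the weight-deviation distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletWD)
```

## The model

tripletWD compares DNA coding sequences without alignment. The unit of
information is the triplet: a coding sequence $G = g_1 g_2 \ldots g_N$ read
in frame 0 decomposes into $M = \lfloor N/3 \rfloor$ consecutive,
non-overlapping triplets $t_1 \ldots t_M$ (a trailing partial codon is
dropped). Each of the $4^3 = 64$ possible triplets carries a fixed weight
$\Psi(t)$, a positive decimal with one fractional digit:

* the **integer part** indexes the amino-acid group the corresponding codon
  encodes (alanine = 1, arginine = 2, ..., methionine = 20, the three stop
  triplets = 21);
* the **fractional part** distinguishes synonymous triplets within a group.

The table is constructed so that any two synonymous triplets are closer in
weight than any two triplets encoding different amino acids. On the
canonical table the largest within-group gap is 0.5 (across the six leucine
triplets) and the smallest between-group gap is 0.7, verified exhaustively
over all 2016 unordered pairs:

```{r}
verify_ordering_rule(build_weight_table())
```

The table ships as a transcribed constant rather than being derived from a
construction rule, because the published mapping is mildly irregular: four
groups (aspartic acid, lysine, threonine, tryptophan) start their
fractional parts at .3 rather than .1. The printed table is what all
published distances depend on, so it is treated as the authoritative
artifact; weights are held internally as exact integers in tenths, making
weight arithmetic exact.

### The 2D representation

A sequence maps to its **plot set** $\{(i, \Psi(t_i)) : i = 1..M\}$:
triplet index on the horizontal axis, weight on the vertical axis. This is
a faithful, invertible-up-to-triplets numeric portrait of the sequence; no
matrix algebra or eigenvalue computation is involved.

```{r}
head(to_plot_set(load_betaglobin()["Human"]), 5)
```

### The weight deviation

For sequences $A$ and $B$ with triplet count vectors
$X, Y \in \mathbb{N}^{64}$ (indexed by the canonical enumeration
$T_1 = \mathrm{GCT}, \ldots, T_{64} = \mathrm{TGA}$), the dissimilarity is
the **weight deviation**

$$\mathrm{WD}(A, B) \;=\; \frac{1}{64} \sum_{i=1}^{64}
  \lvert X_i - Y_i \rvert \, \Psi(T_i).$$

This is a weighted L1 (Manhattan) distance on count vectors scaled by
$1/64$, hence a true metric on profile space: identity, symmetry and the
triangle inequality all hold, and the test suite property-checks them on
hundreds of random profiles. Two consequences worth knowing:

* **Counts are absolute, not frequencies.** Sequences of different lengths
  accumulate length-driven deviation by construction; the benchmark's
  chimpanzee record (376 nt) is penalised against the 444 nt records for
  its missing tail as well as for substitutions.
* **Weighting is compositional, not positional.** Permuting a sequence's
  triplets leaves its profile, and therefore all its distances, unchanged.

The sum is accumulated in integer tenths and divided once by 640
(sum-then-divide), so results are exact to double precision; display
rounding is half-away-from-zero at 4 decimals.

## The 11-species beta-globin benchmark

The package embeds the complete coding sequences of the beta-globin genes
of 11 species (human, chimpanzee, gorilla, black lemur, Norway rat, house
mouse, goat, bovine, rabbit, opossum, Gallus), the standard test bed for
alignment-free comparison methods, plus the published pairwise
weight-deviation matrix for them (`reference_matrix()`). `reproduce()`
recomputes everything end to end and reports per-pair agreement:

```{r, message = FALSE}
res <- reproduce(file.path(tempdir(), "betaglobin"), plots = FALSE)
res$n_mismatch
subset(res$comparison, !match)
```

45 of the 55 pairs agree with the published values to the published
precision (5e-4 after 4-decimal rounding). All 10 residual pairs involve
Gallus. The discrepancy is in the published *input*, not in the method:
replaying the computation with a Gallus variant in which a single AGG codon
reads GAT instead reconciles all ten pairs exactly, while no edit of any
other sequence is needed. Since the published sequence table is the only
authoritative source for the inputs, the package keeps the Gallus record
exactly as printed and reports the residuals rather than silently patching
the data.

```{r}
seqs <- load_betaglobin()
codons <- to_triplets(seqs[["Gallus"]])
codons[which(codons == "AGG")[1]] <- "GAT"  # the single reconciling edit
m2 <- pairwise_matrix(c(seqs[c("Human", "Opossum")],
                        Gallus = paste(codons, collapse = "")))
round(m2["Human", "Gallus"], 4)  # matches the published 16.7109
```

The qualitative conclusions are unaffected: the three smallest distances
are gorilla–chimpanzee (1.1266), human–gorilla (4.3359) and
human–chimpanzee (5.2500), and every distance from opossum or Gallus to any
other species exceeds 11 — consistent with Gallus being the only
non-mammal and opossum the most distant mammal.

## Tree construction

Weight deviations feed directly into standard distance-based tree methods.
UPGMA (average-linkage agglomeration via `stats::hclust`, converted with
`ape::as.phylo`) is the default because the benchmark's published tree does
not state its method and UPGMA makes the testable claim — the primate
clade forms before any primate joins another species — directly checkable
from the matrix. Saitou–Nei neighbor joining (`ape::nj`) is available via
`method = "nj"`; its occasional marginally negative branch lengths are
clamped to zero. Agglomeration ties are resolved by `hclust`'s
deterministic merge order, so identical inputs give identical trees across
runs and platforms.

```{r, message = FALSE}
m <- pairwise_matrix(load_betaglobin())
cat(to_newick(build_tree(m, "upgma")))
```

UPGMA output is ultrametric (all root-to-leaf path lengths equal), which
the suite verifies to 1e-9; exact branch lengths of the published figure
are not a supported claim, only the clade structure derivable from the
matrix.

## Input handling and numerical choices

* **Cleaning.** Input is uppercased, U transliterated to T (so RNA is
  accepted), whitespace and digits stripped. Strict mode (default) rejects
  any other character, naming the first offender and its position;
  permissive mode keeps such characters and excludes the triplets
  containing them from counting.
* **Frame.** Reading frame is fixed at 0 — the benchmark consists of
  complete coding sequences starting at ATG. There is no ORF search,
  strand inference or reverse-complement handling.
* **Trailing bases.** A trailing 1–2 nt partial codon is dropped, with an
  informational message counting the dropped bases (the chimpanzee and
  gorilla benchmark records each shed one base).
* **Indexing.** Plot-set indices are 1-based, in file outputs too.
* **Formatting.** Matrices print at 4 decimals (half-away-from-zero);
  plot-set TSVs print weights with one decimal (their full precision);
  Newick branch lengths use 6 decimals.

## The random-sequence generator

`random_cds(n_codons, seed)` samples triplets uniformly and independently
from all 64, deterministically per seed and without disturbing the
caller's RNG state. It emulates only the alphabet and frame structure of
coding sequences — not codon-usage bias, GC content, start/stop placement
or phylogenetic correlation. Property tests built on it (metric axioms on
500 random profile triples, count oracles on 200 random sequences up to
300 nt, ultrametricity on random matrices) therefore certify the
*algebra* of the implementation, not biological realism; the benchmark
reproduction is what ties the package to real data. The suite's problem
sizes (hundreds of short random sequences, 10,000 codons for the
uniformity check) keep the full run around ten seconds while still giving
the binomial frequency check 3-standard-error resolution per triplet.

## Known limitations

* Only `k = 3`, frame-0, non-overlapping counting is provided; this is the
  definition of the method, not a tunable.
* Weight deviation grows with length differences; it is not a
  substitution-rate estimate and should not be read as an evolutionary
  distance in time units.
* The weighting scheme is the canonical table only; alternative weightings
  are out of scope.
* Figures are best-effort visualisations (points joined by lines by
  default, configurable); they are not pixel-faithful to any published
  rendering.
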