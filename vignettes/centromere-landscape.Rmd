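---
title: "Mapping the centromere landscape: models and methods"
author: "centromap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the centromere landscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centromap)
```

# The scientific problem

In most plants the functional centromere is defined epigenetically: it is
the chromosomal interval occupied by nucleosomes containing the
centromere-specific histone H3 variant CENH3 (CENP-A in animals), not any
particular DNA sequence. On a telomere-to-telomere assembly, the centromere
landscape can therefore be characterised along four complementary axes,
each of which this package implements as a reusable, testable stage:

1. **Functional centromere mapping.** CENH3 ChIP fragments and input
   (bulk chromatin) fragments are counted in fixed windows; the ratio of
   their normalised densities localises the CENH3-bound core, which is
   typically much smaller than the surrounding satellite arrays.
2. **Satellite discovery.** Centromeres are dominated by tandemly
   repeated satellite DNA. Arrays are found de novo, their monomer period
   and consensus estimated, and consensus monomers grouped into families
   named `CentFs<length>` after the consensus length.
3. **Nucleosome phasing.** If CENH3 nucleosomes occupy preferred positions
   on the monomer, the midpoints of ChIP fragments aligned to a trimer of
   the consensus (three concatenated copies) pile up at a small number of
   offsets.
4. **LTR retrotransposon dating.** A full-length LTR retrotransposon
   carries two terminal repeats that are identical at insertion and
   diverge neutrally afterwards, so the per-site divergence $K$ between
   them dates the insertion as $T = K / (2r)$, with $r$ the substitution
   rate per site per year. Comparing centromeric and non-centromeric
   element ages asks whether centromeric invasions are recent.

Telomere counting (tandem `CCCTAAA`/`TTTAGGG` copies at chromosome ends)
completes the chromosome-scale picture.

# Coordinates and containers

Genomes are `Biostrings::DNAStringSet` objects and interval sets are
`GenomicRanges::GRanges`, the native R/Bioconductor containers, which use
1-based closed coordinates. BED and bedGraph files are converted to and
from 0-based half-open coordinates only at the file boundary. The fragment
midpoint is defined on the 0-based frame as
`floor((start0 + end0) / 2)`: a deterministic integer convention that
every downstream stage (window assignment, phasing) shares. `N` bases are
allowed everywhere but never count as matches in any scan or alignment.

# The synthetic-genome generator

Every stage is validated against simulated genomes with exact ground
truth, because no public dataset provides per-base truth for centromere
boundaries, monomer phase, or LTR divergence. The generator
(`chromosome_spec()`, `build_genome()`, `simulate_fragments()`) emulates:

* i.i.d. background sequence at GC 0.36 (the genome-wide GC content
  typical of the study system; only the repeat/non-repeat contrast
  matters downstream);
* terminal telomeric tracts with exact planted copy numbers (chance
  occurrences of the motif in background sequence are scrubbed so
  recovery tests are exact);
* a centromeric tandem array: each monomer copy independently mutated at
  a per-site substitution rate (default 0.02, i.e. ~98% copy identity,
  typical of young plant satellite arrays; up to 0.2 accepted);
* full-length LTR insertions with independent per-LTR substitution loads
  (the molecular clock), optional shared ancestors so elements form
  clades, and optional placement inside the array (emulating the
  fragmented, nested insertions real centromeres accumulate);
* ChIP fragments: a configurable fraction has midpoints planted at
  `array_start + k * period + phase + Normal(0, phase_sd)` — phased
  CENH3 nucleosomes — and the rest is uniform background; input
  fragments are uniform.

The mutation model is substitution-only by design: period, copy-number
and divergence arithmetic stay exact, which is what parameter-recovery
tests need. Real satellite arrays also contain indels and higher-order
repeats; passing these tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to indel-rich variation
(full local alignment via `method = "align"` is available where that
matters). The ChIP fraction knob is a simulation convenience, not a
biological estimate: enrichment tests use 0.6–0.8 (strong signal), while
the repeat-cluster test uses 0.3 or lower because a realistic ChIP
library is mostly background and a dispersed repeat family should score a
ChIP/input ratio near 1.

All randomness flows through one `set.seed()` per entry point, and every
identical `(spec, seed)` pair yields identical bytes — the basis of the
pipeline determinism test.

# Enrichment and centromere calling

Fragment density per window is `(count / total) * 1e6 / 100` — reads per
million divided by 100 — with each fragment assigned to the window
containing its midpoint (unambiguous for boundary-straddling fragments).
The enrichment track is the ratio of ChIP to input densities with a
pseudocount of one fragment-equivalent per track (default), which keeps
sparse windows defined without materially shifting dense ones.

Centromeres are called as maximal runs of windows with
`log2(ratio) >= min_log2` (default 1), allowing `merge_gap` (default 1)
below-threshold windows inside a run, and keeping runs of at least
`min_windows` (default 3). Boundaries snap to window edges, so the
design resolution is one window (100 kb by default). These defaults are a
deliberately conservative, reproducible stipulation — published studies
typically show the enrichment tracks without stating a numeric calling
rule — and all three are exposed in the configuration. When several runs
survive on one chromosome, all are reported and the run with the highest
mean log2 ratio is flagged primary.

`centromere_summary()` reports total/min/max/mean size and percent of
genome, rounding the mean to 1 decimal and the percent to 2 decimals for
reporting (raw values are kept).

# Repeat-cluster enrichment

Reads of 150 bp are sampled at fragment positions and assigned to repeat
cluster consensus sequences; per-cluster ChIP/input ratios (per-million
normalised, pseudocount 1 read) and genomic representation (fraction of
input reads hitting the cluster) feed the selection rule *ratio
strictly > 7 and representation strictly > 0.05%* — strict inequalities
matching the "surpassing"/"exceeding" wording of the selection it
reproduces. An E-value criterion from BLAST-based practice is replaced by
"identity ≥ 0.8 over ≥ 50 aligned bases, best hit only": implementing
Karlin–Altschul statistics would be out of proportion for this step, and
the identity/length proxy is transparent and configurable. Each consensus
is doubled head-to-tail before alignment so reads spanning the tandem
junction are not penalised. Cluster *discovery* (graph-based read
clustering) is intentionally out of scope; consensus sequences come from
the satellite module or from the user.

# Satellite discovery

The detector is a k-mer recurrence periodicity scan written for this
package (the published annotation tools it parallels do not document
reimplementable internals):

1. exact 12-mers are encoded numerically (base-4, exact in doubles) and
   every consecutive recurrence of a k-mer at spacing 50–1000 bp casts a
   vote `(position, spacing)`;
2. the modal spacing seeds a candidate period; supporting votes are
   clustered into candidate regions (gap tolerance `max(3 periods,
   400 bp)` so mutation-dense patches do not split an array);
3. the period is refined by maximising the fraction of positions matching
   their image one period downstream; boundaries come from a windowed
   match indicator against a rough interior consensus (20-bp windows at
   ≥ 70% — a random flank passes at ~3·10⁻⁷ per base, so false extension
   is negligible, while edges remain identifiable only to a few bases
   because random sequence matches any monomer at 25% per base);
4. overlapping candidates are arbitrated by match identity, with
   boundary collisions up to one period trimmed rather than discarded;
5. monomer copies are cut at the estimated period and combined by
   per-column majority vote (ties to the alphabetically first base),
   star-aligning copies to the medoid when lengths differ.

Because a tandem monomer is circular — the array can be cut at any
offset — consensus monomers are reported in canonical (lexicographically
minimal) rotation, and family comparison uses rotation-aware identity on
both strands. Families are named `CentFs<consensus length>`, with letter
suffixes on length collisions. With ≥ 30 copies and per-copy substitution
≤ 5%, the majority consensus equals the planted master exactly (the
per-column error probability is < 10⁻⁶) and the period is recovered
exactly; the false-positive rate on 100-kb random sequences is zero in
the test suite because a candidate needs ≥ 10 co-voting k-mer pairs at
one exact spacing.

`dotplot_matrix()` provides windowed self-similarity (default 100-bp
non-overlapping windows, both strands, ungapped identity ≥ 0.8) for the
qualitative structure comparisons centromere papers present.

# Nucleosome phasing

Fragments are aligned to a trimer (three concatenated consensus copies)
so footprints near monomer junctions are not clipped. Because the trimer
is exactly periodic, any footprint shifted by one monomer is co-optimal;
the implementation prefers the placement whose midpoint lies in the
central copy, so the default central-copy retention (an edge-effect
guard) keeps the full signal. Folding to monomer coordinates, the
midpoint histogram is smoothed with a circular Gaussian kernel
(bandwidth 5 bp) and peaks are local maxima with circular topographic
prominence ≥ 0.25 of the profile maximum, thinned to a minimum
separation of 40 bp. These three constants are stipulations chosen so
that 1–5 planted positions (separation ≥ 60 bp, jitter SD ≤ 15 bp,
n ≥ 5000 midpoints) are recovered exactly in count and to ±5 bp in
position in ≥ 95% of seeded replicates; all are configurable. The monomer
is treated as circular throughout, consistent with its tandem context.

Two mapping backends are provided: the default seed-and-vote ungapped
mapper (exact shared 12-mers vote for a diagonal; the best diagonal is
scored by direct base comparison), which is exact under the
substitution-only model and fast, and full Smith–Waterman local
alignment (`method = "align"`) for indel-containing data. A minimum
aligned length of 50 bp is enforced in both: without it, short spurious
local matches from unrelated families map at systematic positions and
fabricate phase peaks.

# LTR detection and dating

The detector finds pairs of similar same-strand segments: shared 21-mers
at a consistent spacing seed a candidate (k-mers occurring more than 10
times are skipped, which silences satellite arrays; a genuine LTR pair
contributes many consistent seeds, so candidates need ≥ 5), the
spacing-d match indicator is extended to a maximal block, and endpoints
must close with ≥ 5 matches in their terminal 6 bases (random flanks
match at 25% per base). Candidates are filtered by LTR length
(100–3000 bp), element length (1–20 kb) and pair identity (≥ 0.8);
overlapping candidates resolve by identity except that elements nested
wholly inside another's internal region are kept and flagged. The
detector deliberately ignores target-site duplications, `TG...CA`
termini and primer-binding sites: it is a pair-similarity detector,
sufficient for simulator-validated analysis, and externally produced
annotations can be supplied instead wherever elements are consumed.

Divergence uses global alignment of the two LTRs; identity is matches
over aligned columns *excluding gap columns* (noted because published
identity histograms rarely state their gap convention), so
`identity + K = 1` holds exactly for the raw estimator. Jukes–Cantor
correction (`-(3/4) ln(1 - 4p/3)`) is available by flag; raw `K` is the
default to match the "number of differences" reading of the dating
formula. Elements with identity < 0.5 are flagged unreliable and left
out of population summaries. The default clock is `r = 1.3e-8`
substitutions/site/year, a widely used plant LTR rate; it is always
configurable and recorded in output metadata, and `T` scales as `1/r`.
Population comparison reports per-class median identity, a two-sided
Wilcoxon rank-sum test, and binned histograms. Clades are single-linkage
clusters of whole-element global-alignment identity at a 0.7 threshold —
an intentional approximation of a full phylogeny, adequate for counting
distinct ancestries.

# Pipeline and report

`run_pipeline()` executes simulate/load → telomeres → enrichment →
centromere calls → satellites → cluster scoring → phasing → LTR dynamics
→ report, writing plain-text outputs (TSV/JSON/BED/bedGraph/FASTA) plus
a `MANIFEST` of stage status. Without fragment input the
enrichment-dependent stages are skipped and recorded as such. A stage
failure aborts with the stage name after the MANIFEST is written, so
partial outputs survive. Reruns with identical configuration and seed
are byte-identical.

The per-chromosome report mirrors the familiar published layout —
chromosome size, centromere location and size (Mb, one decimal), and
satellite-array span — with the array span summed within ±2 Mb of the
call. The flank is needed because satellite arrays consistently exceed
the CENH3-bound core; it is configurable, and its exact published
definition is not stated, so this column is a documented stipulation.

# Problem sizes used in the tests

Unit and acceptance tests run on genomes of 0.1–10 Mb with 10⁴–10⁵
fragments, monomer lengths spanning 54–732 bp, and 20–50 seeded
replicates per recovery property; these sizes give the binomial and
multinomial margins quoted above while keeping the default test suite
fast. The pipeline integration fixture uses two 0.8-Mb chromosomes with
70-kb centromeres and 20-kb windows — geometry chosen so the centromere
spans several windows and the satellite share of the genome stays in the
single-digit percent range, as in real genomes.

# Known limitations

* Substitution-only simulation: indels, higher-order repeats and
  sequencing error are not modelled; recovery guarantees are with
  respect to that model.
* Boundary resolution is one window for centromere calls and a few bases
  for array edges (exact edges are unidentifiable against random flanks).
* The LTR detector reports structural candidates only; superfamily
  classification and solo-LTR recombination analysis are out of scope.
* Clade clustering approximates, but is not, a phylogeny.
* `uniquely mapped` read filtering happens upstream of this package's
  canonical BED input; a mapping-quality threshold applies only when
  alignments are converted externally.
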