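---
title: "Mining a satellitome from low-pass shotgun reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining a satellitome from low-pass shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Satellite DNAs (satDNAs) are non-coding sequences organised as long
head-to-tail arrays of a repeated unit (the monomer), typically concentrated
in heterochromatin and often massively amplified on degenerate sex
chromosomes such as the snake W. Because arrays collapse in genome
assemblies, the standard way to characterise a *satellitome* — the full set
of satDNA families of a genome — is to work directly on unassembled,
low-pass (< 1x) shotgun reads: discover candidate monomers in a read sample,
remove the reads they explain, and repeat until no new family appears; then
quantify each family by masking a larger read sample against the catalog and
summarise its divergence structure as a Kimura-2-parameter (K2P) repeat
landscape. In a ZW species, comparing female and male read libraries adds an
in-silico analogue of comparative genomic hybridisation: a family present in
the female but absent in the male library is a W-linked candidate.

`satmine` implements this procedure end to end, together with a seeded
synthetic-data generator that plants satellite families of known monomer,
abundance, divergence and linkage into female/male genomes, so that every
stage can be validated against ground truth.

## Sequence model and conventions

A satellite monomer is a circular unit: two monomers describe the same
family if one is a rotation of the other, on either strand. All comparisons
therefore go through the *canonical monomer* — the lexicographically
smallest string among all rotations of the sequence and of its reverse
complement (`canonical_monomer()`, Booth's least-rotation algorithm) — or
through `rotation_identity()`, which aligns the shorter sequence glocally
against the self-concatenation (dimer) of the longer one on both strands, so
that any phase of the circular unit can match.

Alignment scoring is fixed package-wide for reproducibility: match +1,
mismatch −1, gap open −2, gap extend −1; identity is matches over aligned
columns, gap columns included. `N` never matches — it is booked as a
transversion for identity purposes and excluded from the K2P site count.

Divergence uses the plain Kimura 2-parameter distance

$$ d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big), $$

with transition proportion $P$ and transversion proportion $Q$ over ungapped,
N-free aligned sites; inputs with $1-2P-Q \le 0$ or $1-2Q \le 0$ return the
saturation marker (`Inf`), which the landscape routes to its overflow bin.
Some repeat-annotation tools report a CpG-adjusted K2P; this package
deliberately does not (the adjustment is specific to methylated genomes and
would change landscape positions by fractions of a bin at the divergences
simulated here).

## The synthetic-data generator

`sim_spec()` defines the study conditions; its defaults are the conditions
under which the package's acceptance checks run and were chosen once, up
front, to emulate a realistic low-pass snake satellitome experiment:

* a 2 Mb haploid genome, background i.i.d. at GC 0.5;
* five planted families spanning the interesting regimes — repeat unit
  lengths (RULs) 25, 48, 160, 170 and 200 bp, genome fractions 2–8%,
  per-copy K2P divergences 1–5%, transition:transversion ratio 2 — with the
  160 bp family W-linked (present only in the female genome), mirroring a
  subtelomeric W satellite;
* paired 100 bp reads at 0.2x coverage per haploid genome, insert
  300 ± 30 bp, per-base error 0.001, constant Q30 qualities.

Copies are mutated i.i.d. per site at the rate that makes the *expected*
K2P distance from the master monomer equal the requested divergence (the
closed form solved for the substitution rate given kappa); no indels are
introduced, so the truth divergence stays well defined under K2P and
assembled contigs stay in register. Arrays are uniform-phase head-to-tail
tandems split over four loci; a `dispersed` arrangement plants every copy
singly, providing the decoy that the tandem filter must reject. Diploidy is
implicit: one haploid sequence per sex, W arrays only in the female, and
coverage interpreted per haploid genome — sufficient for abundance-ratio
logic.

What the generator does *not* emulate: platform-specific error and quality
profiles, PCR duplicates, indel polymorphism inside arrays, higher-order
repeat structure, and a transposable-element background. Passing tests
therefore demonstrate the correctness of the pipeline's logic under the
stated model, not discovery performance on real libraries, where the
detector's cluster-based ancestors remain the reference.

## Discovery: two complementary paths

Reads are quality-trimmed (sliding window, Trimmomatic-style: cut before the
first 4-base window with mean quality < 20; pairs with a mate < 36 bp are
dropped) and sampled 2 × 500,000 pairs per iteration at full scale (the
desk-scale runs in this package use their whole, much smaller pools).

**Short monomers (RUL ≤ read/2)** betray themselves inside single reads:
`detect_period()` reports the smallest lag `p` at which at least `1 − tau`
of positions agree with their `p`-shifted partner (default `tau` 0.1). One
point to note: a single substitution breaks *two* lag-`p` comparisons, so a
read carrying `m` mutations over `L − p` comparisons needs
`tau ≥ 2m/(L−p)`. Internally periodic monomers are reported at their
divisor period — a documented convention. Copies are tiled windows of
length `p`, each canonicalised, and `cluster_candidates()` groups them
greedily: unique copies in order of decreasing multiplicity, each joining
the first cluster whose consensus it matches at the variant tier (≥ 0.95),
else founding a new cluster, with the consensus recomputed by per-column
majority vote (ties alphabetic) after every assignment. Because equal-length
copies carry no indels, the hot-path identity is computed as the best
cyclic-shift match (exact, C++) rather than by alignment. At 5% divergence
the 0.95 variant threshold necessarily fragments a family (copy-to-consensus
identity straddles 0.95), so fragment clusters whose consensus sits in the
*family* tier (> 0.80) of a larger sibling are folded into it before the
support filter — the family tier, not the variant tier, defines family
membership.

**Long monomers (RUL > read/2)** cannot show two copies in one read — the
regime of, e.g., a 324 bp monomer on 100 bp reads. Here the package uses the
k-mer structure of the sample: satellite monomers are covered tens to
hundreds of times in monomer space even at 0.2x genome coverage, so reads
whose 17-mers are *repetitive* (multiplicity ≥ 8) mark arrays. A read joins
the assembly pool when ≥ 30% of its k-mers are repetitive *and the same
holds for its mate* — at 5% divergence only ~40% of a copy's 17-mers remain
intact (0.95^17), which sets the 0.3 scale, and the mate condition restricts
the pool to fragments lying wholly inside arrays, keeping contigs free of
flanking background. Contigs grow by greedy overlap extension anchored on
exact shared k-mers (substitution-only, matching the generator; overlap
≥ 40 bp at ≥ 0.85 identity, which tolerates two 5%-diverged copies), the
contig's period is called with a looser tolerance (0.25, since adjacent
contig copies come from independently diverged genomic copies), and the
monomer is the majority vote over the contig's tiled windows. The
`min_kmer_count` default scales with sample depth and is the knob to adjust
for other sampling designs.

Candidates from both paths are merged at the family tier, then screened:
`tandem_stats()` counts supporting reads (best local hit against a tandem
reference at ≥ 0.8 identity) and the fraction with *tandem evidence* —
either two full copies inside the read, or, for monomers longer than half a
read, a supporting mate (a lone dispersed copy can hold one read but not a
whole 300 bp fragment). `tandem_filter()` keeps candidates with tandem
fraction ≥ 0.8 and RUL in [5, 1000]; this is the stand-in for the screening
step that removes dispersed repetitive elements such as multigene families,
and the declared replacement for the cluster-shape criteria of the
graph-based detectors, so family counts on real libraries may differ.

## The mining loop, tiers and nomenclature

`run_mining()` iterates sample → discover → merge → filter. New candidates
are placed by rotation identity against the working catalog using the
published similarity tiers — variants (> 95%), families (80–95%],
superfamilies (50–80%] — with upper bounds inclusive so the three intervals
partition (0.5, 1]: > 0.95 is an occurrence of an existing variant (logged),
(0.80, 0.95] a new named variant of its family, ≤ 0.80 a new family. Reads
matching any family consensus at ≥ 0.90 identity over ≥ 80% of their length
(both inclusive; best local alignment against the tandem reference, both
strands) are then removed, mates together, and the loop stops when an
iteration founds no family. Those removal thresholds are declared
inventions surfaced in `mining_config()` — the original read-removal tools
do not publish theirs. The female library is mined by default, being the
superset containing W-linked repeats.

Families are ranked by quantified abundance and named
`<Prefix>Sat<NN>-<RUL>`, most abundant first (`PkoSat01-168` style).
`summary_stats()` reports median/min/max RUL and the A+T fraction over the
unweighted concatenation of consensus monomers — the simplest reading of
how such catalog statistics are usually quoted; whether published values
weight by abundance is typically unstated.

`group_superfamilies()` deliberately departs from the gapped identity: under
the package's permissive gap costs the glocal identity of two *unrelated*
random monomers of similar length measures 0.55–0.59, above the 0.50
boundary, and a short monomer matching some window of a long one scores
higher still. Superfamily links therefore use the best ungapped cyclic-shift
match normalised by the longer RUL, which puts unrelated pairs near 0.25–0.4
and leaves genuinely related monomers (no indel divergence in this model) in
their correct tier; grouping is single-linkage.

## Quantification and landscapes

`mask_reads()` aligns every read locally against each family's tandem
reference on both strands (an exact-k-mer prescreen, k = 12, skips reads
sharing no k-mer with the reference — a seed-and-extend heuristic that can
only lose hits far below the identity floor) and keeps one best hit per read
(aligned-bp × identity score; ties to the lexicographically first name) at
≥ 0.70 identity over ≥ 30 bp. Abundance is the proportion of aligned read
bases among all analysed bases — best-hit-only, so no base is counted
twice; mates count as independent sequences, matching the "2 × N reads"
convention of read-based repeat quantification. `landscape()` bins each
hit's bp by its read-to-consensus K2P distance (1% bins, overflow at 0.5,
empty bins kept up to the last occupied one) and emits both
fraction-of-family and fraction-of-total columns, since published landscapes
normalise either way. Note the geometry: copies are planted at divergence
*d* from the master, the mined consensus converges to the master, and reads
add sequencing error, so landscape modes sit near *d*, slightly above.

## Cross-library screening and W detection

`screen_library()` calls a family present in another library when it
attracts ≥ 5 supporting reads and ≥ 1e-5 of the analysed bases — a
conservative floor above sequencing-error noise, declared as an invention
(the cross-species assay it mirrors was PCR, which has no computational
threshold to copy). `sex_bias()` computes
`log2((female + eps)/(male + eps))` per family (eps 1e-7, capped at ±20)
and flags families at ratio ≥ 1 as W candidates; a truly W-linked family
has male fraction 0 and hits the cap, while autosomal families fluctuate
within ±1 at the bp counts involved.

## Numerical and design choices

* Sampling, mutation, fragment placement and errors all flow from one
  integer seed; sub-streams are derived arithmetically so the two sexes and
  the per-iteration samples are independent but reproducible. Libraries are
  read whole and then sampled (the desk-scale inputs fit comfortably in
  memory; a streaming reservoir would only matter for full-size archives).
* Report tables print numerics at 6 significant digits for clean diffs;
  catalog FASTA headers carry full precision so write→read→write is
  byte-stable.
* Degenerate inputs: empty catalogs error in quantification and comparison;
  an empty post-trim pool errors in mining; zero-family simulations produce
  valid background-only genomes.
* Desk-scale problem sizes (2 Mb genome, 0.2x, 2,000 pairs; 80–400 kb
  genomes in unit tests) were fixed as the package's validation conditions;
  the full-scale defaults (2 × 500,000 mining pairs, 2 × 5,000,000
  quantification pairs) remain in the configs for real libraries.

## Known limitations

* Discovery sensitivity bottoms out at `min_support` (10 reads): families
  below ~0.5% abundance at 0.2x coverage are invisible by design.
* The long-monomer assembler assumes substitution-only divergence between
  copies; indel-rich satellites would need gapped overlap extension.
* Monomers whose length exceeds the assembly contig cap / 2 (default
  1,000 bp) cannot be called.
* `detect_period` reports divisor periods for internally periodic monomers;
  such families are catalogued at the smaller unit.
* Cross-library "presence" is read-based and not calibrated against
  PCR/hybridisation assays; concordance with wet-lab detection on real
  accessions is not asserted anywhere in this package.
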