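---
title: "Methods and design of genefamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of genefamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

genefamkit implements a complete genome-wide characterization workflow for
the AP2/ERF transcription-factor superfamily: domain-based family
identification, architecture and sequence-based subfamily classification,
duplicate-pair detection with Ka/Ks selection analysis, neighbor-joining
phylogenies with bootstrap support, repression-motif and promoter
cis-element screening, and expression analysis of RNA-seq FPKM matrices and
qPCR Ct tables. This vignette explains the models and numerical choices
behind each stage, what the bundled simulator does and does not emulate,
and the known limitations.

## Domain detection

AP2/ERF membership is defined by the ~60-residue AP2 DNA-binding domain;
RAV proteins additionally carry a B3 domain. Detection uses a
position-specific scoring model per domain: every alignment column stores
log-odds scores in bits,

$$\mathrm{score}(c, a) = \log_2 \frac{n_{a,c} + \kappa\, b_a}{(n + \kappa)\, b_a},$$

with residue counts $n_{a,c}$, pseudocount weight $\kappa$ (default 1) and
background frequencies $b_a$ (uniform by default). Scanning is gap-free:
the profile is slid over the protein, per-column scores are summed, and
placements above a bit-score threshold are greedily reduced to a
non-overlapping set by descending score. Windows overhanging a sequence end
are scored on their matched columns only, which lowers their coverage and
lets the downstream coverage filter (default 0.7) remove partial domains.

We chose gap-free window scoring over a full profile HMM with
insert/delete states deliberately: the bundled synthetic fixtures are
gap-free, so window scoring is exact for them, and real-genome use is
served by `read_domtblout()`, which imports HMMER3 per-domain tables with
envelope coordinates converted to 0-based half-open and the independent
E-value as the hit E-value.

Score thresholds are calibrated on an explicit null: `calibrate_threshold()`
scores a few hundred background-drawn proteins, fits a Gumbel law to the
per-sequence maximum scores by the method of moments
($\beta = s\sqrt{6}/\pi$, $\mu = \bar{x} - \gamma\beta$), and returns the
score at which the expected number of null hits per search equals the
target E-value (default $10^{-5}$, the conventional domain-search cutoff;
the search space scales per protein as $L - W + 1$ windows). The same
Gumbel parameters convert observed hit scores into per-protein E-values.

The bundled AP2 (58 columns) and B3 (90 columns) profiles are built from
*synthetic* seed alignments shipped with the package. They echo landmark
features of the real domains (the YRG/WLG/RAYD-like segments of AP2, the
conserved P/L/D/G/W positions of B3) but are reproducible stand-ins, not
Pfam-derived data; all fixture files carry `synthetic` in their names.

## Subfamily classification

Architecture rules follow the classical definition: one AP2 domain = ERF
clade, two AP2 domains (any linker length; the canonical 25-residue linker
is descriptive, not a filter) = AP2 subfamily, AP2 + B3 = RAV. A B3 domain
without AP2 is anomalous and reported as UNCLASSIFIED rather than silently
dropped.

The ERF clade is refined into ERF, DREB, DRF and SOLOIST by a
nearest-labeled-reference rule: the hit's domain residues (aligned to
profile columns by the gap-free scan) are compared to a labeled reference
set by ungapped column-wise identity, ties broken by the fixed priority
ERF > DREB > DRF > SOLOIST and then file order; a best identity below 0.25
falls back to SOLOIST. We chose nearest-reference over fixed diagnostic
residues because published classifications delegate the split to
criteria established in *Arabidopsis* and rice without printing an
operational rule; a reference set makes the rule explicit, swappable and
testable.

In the synthetic fixtures, DREB, DRF and SOLOIST are concrete variants of
the base AP2 profile: DREB and DRF each pin 14 fixed signature columns to
fixed alternative residues, and SOLOIST replaces a fixed 35% of columns
with background-drawn residues chosen once when the fixtures were built.
Making the SOLOIST divergence a fixed pattern (rather than fresh random
residues per gene) is what makes nearest-reference classification
well-posed: with per-gene random divergence a SOLOIST query is closer to
ERF references than to any SOLOIST reference, and no identity cut can
separate it without also misclassifying genuine ERF genes. The divergence
fraction is the package's knob for the "divergent single-domain clade"
concept.

Family members are named by chromosomal order with the sort key
(chromosome number 1–7, subgenome A before B, start coordinate), yielding
`TtAP2/ERF-001`-style names, and tabulated over all 14 chromosome labels
with subgenome totals.

## Duplicates and Ka/Ks

Duplicate pairs are gene pairs whose global CDS alignment identity is
*strictly* greater than 85%. Alignment is Needleman–Wunsch with affine
gaps (match +2, mismatch −1, gap open −5, gap extend −1; a gap of length
$L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$), delegated to the
Biostrings dynamic-programming engine; identity is matches over all
aligned columns, a definition we document because published pipelines
rarely state their denominator. Clusters of duplicates are connected
components of the retained-pair graph.

Ka/Ks uses the Nei–Gojobori method with Jukes–Cantor correction, the
classical default of DnaSP-style analyses. Potential synonymous sites per
codon are the per-position synonymous fractions of the nine
single-nucleotide changes (changes to stop codons count as nonsynonymous),
so $s + n = 3$ per codon exactly. Differences between codon pairs are
averaged over all orderings of the differing positions (1, 2 or 6
pathways), excluding pathways through stop codons and renormalizing; if
every pathway is blocked, all are used. Alignment triplets containing gaps
are removed (complete-codon pairwise deletion), as are stop-containing
triplets. Proportions are corrected with
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined at $p \ge 0.75$
(flagged saturated). Selection is called purifying ($\omega < 1$), neutral,
positive, or undefined ($K_s = 0$). Both counters are verified in the test
suite against exhaustive enumeration over all 61 sense codons and all
61×61 codon pairs.

## Phylogeny

`nj_tree()` implements Saitou–Nei neighbor joining: the pair minimizing
$Q(i,j) = (r-2)d_{ij} - R_i - R_j$ is joined, ties resolved by the
smallest index pair; negative branch lengths are clamped to zero with the
deficit transferred to the sister branch; the final tree keeps the
unrooted root trifurcation. NJ is consistent on additive distances, which
the suite exploits: random additive matrices from random 8-leaf trees must
be recovered exactly, and results are cross-checked against an independent
NJ implementation.

Distances for domain trees are p-distances on the profile-anchored,
gap-free AP2-domain columns — this avoids a full multiple-alignment stage
while keeping columns comparable. Bootstrap support resamples columns with
replacement (default 1000 replicates, the conventional choice; the
pipeline default is 200 to keep the bundled run short) with replicate RNG
streams derived from one seed by counter offset, and scores each internal
bipartition by its replicate frequency. Clades transfer from labeled
reference leaves by nearest patristic distance, ties resolved
alphabetically.

## Protein properties

Molecular weight sums average (not monoisotopic) residue masses plus one
water, matching the ProtParam convention; the mass table is bundled.
The theoretical pI solves the net-charge equation under the Bjellqvist
(ExPASy-compatible) pKa set — positive terms from the N-terminus, K, R, H;
negative from the C-terminus, D, E, C, Y — by bisection on pH ∈ [0, 14]
to |charge| < 1e-4. The charge function is monotone in pH, so bisection
always converges; the suite checks agreement with a fine-grid
(Δ = 1e-4) scan to within 1e-3 pH units. Per-column conservation tables
report frequencies, information content $\log_2 20 - H$ and the modal
consensus (alphabetical tie-break); these tables are the tested artifact
behind sequence logos — rendering is left to the caller.

## Motifs and promoters

Three repression/activation motifs are screened in proteins: [RK]LFGV,
the EAR-type DLN motif in both its strict (FDLNLPP) and generalized
([LF]DLN[LF]) spellings — both appear in the literature, so both are
reported under distinct names — and EDLL. All overlapping matches are
reported; nothing is greedily consumed, which keeps results
order-independent. Promoters are the 1500 bp immediately 5' of the start
codon (reverse-complemented for minus-strand genes, truncated with a
warning at chromosome edges), scanned on both strands for the
dehydration-responsive element [AG]CCGAC, ABRE B (TCCACGTCTC), re2f-1
(GCGGGAAA) and the ACGT motif (GTACGTG); minus-strand hits are reported in
promoter coordinates. N matches nothing.

## Expression and qPCR

Genes below 0.5 FPKM in every sample are removed (published pipelines
state the elimination of unexpressed genes without a cutoff; 0.5 is our
configurable operationalization). Heatmap values use log2(FPKM + 1).
Tissue specificity uses the tau index on log2-transformed values,
$\tau = \sum_i (1 - x_i/x_{\max})/(n-1)$: tissue-specific at
$\tau \ge 0.8$ with peak FPKM ≥ 1, ubiquitous at $\tau \le 0.2$ with all
tissues ≥ 1, otherwise mixed. The thresholds formalize a qualitative
grouping and are configuration keys, chosen so that genuinely
single-tissue genes and flat profiles separate cleanly. Stress calls use
log2 fold change against the single control column with pseudocount 0.5
in numerator and denominator (avoids division by zero) and a ±1 log2
threshold; genes below 0.5 FPKM in both columns are not called. No
replicate statistic is attached to these RNA-seq calls — the design has a
single accession per condition, so the fold-change rule is an explicit
stand-in.

qPCR analysis follows the 2^−ΔΔCт method: per-replicate
ΔCt = Ct(target) − Ct(reference), ΔΔCt = mean ΔCt(treatment) − mean
ΔCt(control), relative expression 2^−ΔΔCt, with a two-sided equal-variance
Student's t-test on the replicate ΔCt values (Welch available by flag) and
the conventional p < 0.05 mark. Identical replicate sets have zero
variance, where the t statistic is undefined; the p-value is then resolved
by the mean difference (1 when equal). Adding any constant to every Ct
leaves the estimate unchanged, which the suite asserts.

## The simulator: what it emulates and what it does not

`simulate_family_genome()` generates the study conditions end to end:
domain instances sampled column-wise from the profile emissions, embedded
in uniform-background flanks behind an initiator methionine
(uniform background maximizes contrast with high-information profile
columns); coding sequences by seeded uniform synonymous back-translation
(no codon-usage table — the tests do not need one); gene placements on
chromosomes 1A–7B with intergenic gaps > 3000 bp so that 1500-bp promoter
windows never collide; duplicated pairs created by re-deriving one gene of
a same-subfamily pair from the other through `mutate_duplicate()`.

`mutate_duplicate()` proposes single-nucleotide changes uniformly
(position and alternative base), accepts synonymous proposals at rate 1
and nonsynonymous at rate ω, and rejects-and-redraws proposals that would
create stop codons — this keeps the ORF valid without materially biasing ω
at the scales used. The number of evaluated proposals is
$3 C \cdot K_s^{\text{target}}$, so accepted synonymous events per
synonymous site approximate the target; realized event counts are recorded
as the recoverable truth. Defaults — target Ks 0.05 (≈96% identity, well
inside the duplicate threshold) and an ω grid of 0.1/0.3/0.5/0.8 — mirror
a family evolving under predominantly purifying selection.

Expression defaults: five tissues (leaf, root, stem, grain, spike),
control plus 1 h/6 h drought and heat; log-normal baselines around
10 FPKM with multiplicative noise (sdlog 0.2); tissue-specific genes are
elevated 20-fold in their tissue over a low (~0.2 FPKM) off-tissue
baseline — tissue specificity in real data means low elsewhere, and this
is also what makes the tau threshold attainable; stress-responsive genes
change 8-fold versus control, a strong but realistic response for
stress-inducible transcription factors. Ct tables use
Ct = offset − log2(expression) + N(0, 0.2) on both the target and the
constant-expression reference gene, three biological replicates.

The simulator does **not** emulate: intron structure, codon usage,
tandem-array placement, read-level noise (FPKM values are drawn, not
quantified from reads), partial or gapped domain copies, or inter-genome
homoeologue structure. Passing tests on these fixtures therefore
demonstrate the correctness of the algorithms under their stated models,
not robustness to every artifact of real genome annotations — real-genome
domain calls should come through the HMMER interoperability path.

A note on precision: with Ct noise of 0.2 cycles and three replicates, the
standard deviation of a ΔΔCt estimate is ≈ 0.23 cycles, so a 4-fold change
is estimated within ±0.5 cycles of ΔΔCt in ≈95–97% of experiments, but
within ±0.5 of the *linear* fold value (3.5–4.5) only ≈55–60% of the time;
reaching 95% on the linear scale would need per-Ct noise below ≈0.11
cycles or more replicates. The verification script reports both rates.

## Problem sizes and reproducibility

The bundled analyses run at desk scale by choice: the default simulated
family has 60 genes (47 domain-positive) across all 14 chromosomes, six
duplicate pairs, 200 calibration shuffles and 200 bootstrap replicates in
the pipeline configuration; simulation-recovery checks use 300-codon
sequences with 200 replicates per ω. Every random draw descends from a
single integer seed (replicate streams by counter offset), and a repeated
run writes byte-identical artifacts, which the manifest checksums in each
run directory make easy to verify. Headline catalogue numbers from any
particular real genome (gene counts per subfamily, per-chromosome totals,
Ka/Ks ranges) are genome-dependent and are deliberately not asserted
anywhere.

## Limitations

- Gap-free window scanning cannot model insertions/deletions inside a
  domain; real searches should import HMMER3 results.
- The ERF/DREB/DRF split is only as good as the reference set; the bundled
  references are synthetic and should be replaced with curated domains for
  real analyses.
- Duplicate clusters are connected components of the identity graph, which
  need not coincide with phylogenetically defined duplication groups.
- NG86 assumes equal mutation rates among nucleotides; the simulator
  satisfies this by construction, real data need not.
- The stress-response calls are threshold rules on single-accession FPKM,
  not a replicated differential-expression statistic.
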