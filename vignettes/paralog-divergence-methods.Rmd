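---
title: "Methods: divergence and diversity of tandem gene duplicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence and diversity of tandem gene duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdiv)
```

## Scope

`paralogdiv` analyses pairs of gene paralogs — the motivating system is the
tandemly duplicated *Arabidopsis thaliana* β-COP coatomer genes — through
four connected questions: are the copies physically adjacent (tandem
duplication), how long ago did they diverge (4DTv, Ka/Ks), how variable is
each copy across a panel of inbred accessions (per-gene π with
annotation-impact filtering), and what do the accompanying bench assays
measure (electrolyte leakage, cotyledon greening, comparative Ct). Every
estimator has a matching simulator with recorded ground truth, so the whole
pipeline can be validated without external data.

## Tandem classification

Two genes on the same chromosome are called a tandem duplication when their
physical distance is strictly below a threshold, 2,500 bp by default.
"Physical distance" between two gene models has no single standard
definition, so both candidates are computed and reported:

* the **intergenic gap**, `max(0, max(start) − min(end) − 1)` — zero for
  overlapping genes; this is the default classification metric;
* the **start-to-start distance**, `|start_a − start_b|`.

The rule is deliberately naive (strand-agnostic, strict `<`); it mirrors
how tandem arrays are screened in comparative surveys, where a distance
cutoff stands in for full synteny analysis. Reporting both metrics makes
cutoff sensitivity inspectable: a pair can be tandem under one metric and
not the other, and summaries of tandem-pair distances can legitimately
exceed the cutoff when computed under the other metric.

## Codon alignment by threading

Divergence statistics require an in-frame pairwise codon alignment. Rather
than aligning nucleotides directly, `thread_codon_alignment()` takes a
protein alignment (from any aligner; `estimate_divergence()` uses
Needleman–Wunsch global alignment with BLOSUM62 via Biostrings) and
back-translates it: each residue becomes its source codon, each gap a whole
codon `---`. This guarantees frame integrity — gaps can never split a codon
— and reduces the bespoke content to the distance computations themselves.
A terminal stop codon on either CDS is trimmed; an internal stop is an
error. Codon columns containing a gap or an ambiguous base (`N`) are
excluded from all counts. For two sequences, "all 4D sites" and "4D sites
in gap-free columns" coincide, since a 4D site already requires both codons
to be ungapped.

## 4DTv: transversions at fourfold-degenerate sites

A codon column yields a fourfold-degenerate (4D) site when both codons
agree at positions 1–2 and the shared prefix belongs to a fourfold codon
family (CT, GT, TC, CC, AC, GC, CG, GG). Prefix agreement guarantees that
any third-position difference is synonymous in both backgrounds; columns
whose prefixes differ are excluded even if each prefix is individually
fourfold. The raw statistic is

$$Q = \frac{\text{transversion differences at 4D sites}}{\text{4D sites}},$$

with transversion meaning a purine↔pyrimidine difference. Because repeated
transversions at one site can revert the purine/pyrimidine class, $Q$
saturates at 1/2; the Kimura-type transversion distance

$$\hat d_{4DTv} = -\tfrac{1}{2}\,\log(1 - 2Q)$$

inverts that two-state process. The correction is undefined at $Q \ge 1/2$
(flagged `saturated`) and is exposed as a pluggable function so an
alternative multiple-hit correction can be swapped in. Cohorts of pairs are
classified as *recent* (corrected < 0.01), *ancient* (> 0.5), *saturated*,
or *intermediate* — the conventional reading of 4DTv as a duplication-age
clock.

## Ka/Ks by Nei–Gojobori (1986)

`ng86_kaks()` implements the unweighted-pathway NG86 estimator:

* **Site counts.** Each codon contributes synonymous sites equal to the
  fraction of its nine single-nucleotide changes that preserve the amino
  acid; changes into a stop codon count as nonsynonymous. `S` is averaged
  over the two sequences and `N = 3·codons − S`.
* **Difference counts.** Codons differing at 2–3 positions are resolved by
  equal-weight averaging over all minimal substitution pathways; pathways
  passing through a stop codon are excluded (if every pathway is blocked,
  all are used). The per-pair values are precomputed for all 64×64 ordered
  codon pairs, so alignments reduce to table lookups.
* **Correction.** `ps = Sd/S` and `pn = Nd/N` are corrected with
  Jukes–Cantor, $d = -\tfrac34 \log(1 - \tfrac43 p)$; `ps` or `pn` ≥ 3/4 is
  a saturation error, and ω = Ka/Ks is undefined at Ks = 0.

The stop-codon conventions are stated because published NG86
implementations differ on them; the package's test oracle (an independent
brute-force pathway enumerator) shares these stated conventions.

NG86 assumes unbiased mutation. Under transition bias (κ > 1) it
systematically underestimates ω, because transitions at third positions are
disproportionately synonymous — a known property of the estimator, not a
defect of this implementation. The calibration tests therefore run the
neutral-recovery cohort at κ = 1, where the estimator's assumptions match
the generator; even there ω̂ sits slightly below 1 because proposals into
stop codons are rejected by the generator while NG86's `N` still counts
stop-directed changes as nonsynonymous capacity.

## Nucleotide diversity (π), VariScan style

For each segregating site with per-site haploid sample size $n$ and allele
frequencies $p_i$, the unbiased heterozygosity is

$$h = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

whose sum over sites equals the mean number of pairwise differences among
the sampled haplotypes (tested against a direct all-pairs enumeration).
Two normalizations of that sum are meaningful and differ by orders of
magnitude: per base pair of the gene interval (`per_site`, the classical
π) and per segregating site (`per_segregating_site`). **The normalization
argument has no default** and pipeline reports always carry both columns:
per-gene diversity values for compact genes are frequently quoted without
stating the denominator, and forcing the choice surfaces the ambiguity
instead of hiding it. The gene window (whether UTRs/introns are included)
is likewise the caller's choice, via explicit interval coordinates.

Panels of inbred accessions are treated as haploid: a homozygous diploid
genotype contributes one allele. Heterozygous calls — rare residual
heterozygosity in selfing lines, unresolvable to a single allele — are
treated as missing, like `./.`; both are excluded from the per-site $n$
(complete-case per site), and sites left with $n < 2$ are dropped and
logged. Multiallelic SNPs are decomposed into per-ALT records for
annotation purposes but counted once as a segregating site, with $h$
computed from the full allele-count vector. Indels and other non-SNP
records are skipped with a logged count.

SnpEff-style `ANN` annotations supply each variant's effect and impact
class; the filter keeps MODERATE + HIGH by default (missense, frameshift,
premature stop). Annotation selection is deterministic: the first entry
matching the queried gene (preferring an allele match), else `unknown`.
Deleteriousness is consumed from an external predictor's table (variant →
0/1), never computed. Cross-gene co-occurrence asks whether any accession
carries at least one deleterious variant in each gene, from the 0/1
accession-by-variant matrices.

## Assay formulas

* Electrolyte leakage: $EL = (S_1 - S_0)/(S_2 - S_0) \times 100$ from
  conductivities before shaking, after shaking, and after autoclaving
  (total lysis). Unit-free; affine rescaling of all three readings cancels.
  Values outside [0, 100] are returned but flagged.
* Greening rate: $100 \cdot n_{green}/n_{total}$.
* Comparative Ct: fold change $2^{-\Delta\Delta Ct}$ with perfect-doubling
  efficiency, the assumption of the comparative-Ct method; technical
  replicates are averaged to one Ct first, biological replicates summarized
  as mean ± s.e.m.

## Simulators and what they do (not) emulate

**Codon pairs** (`evolve_codon_pair`). A uniform stop-free ancestor evolves
along two branches of length $d/2$. Events are proposed as
Poisson($\tfrac d2 \cdot$ sites) per branch; each picks a uniform site and
proposes the transition with probability $\kappa/(\kappa+2)$ (each base has
one transition and two transversion alternatives), otherwise a uniform
transversion. Proposals creating stops are rejected; amino-acid-changing
proposals are accepted with probability min(1, ω). Thus $d$ is the expected
*proposed* substitutions per site along the full path; at 4D sites under
ω = 1 every proposal is accepted, so the realized transversion distance is

$$d \cdot \Pr(\text{transversion}) = d \cdot \frac{2}{\kappa + 2},$$

e.g. 0.15 at $d = 0.3,\ \kappa = 2$ — the analytic expectation the
4DTv-recovery tests check (the purine/pyrimidine class flips at exactly the
transversion events, so the corrected distance estimates their count per
site). With ω < 1 the identity still holds at sites whose codon prefix
stays fourfold-degenerate; histories that pass through non-4D prefixes
introduce a bias far below the ±0.02 acceptance band at these divergences,
which is why the recovery cohort uses ω = 1. Truth is recorded as
*realized* accepted-event counts, not expectations, separating estimation
error from Monte-Carlo noise. The model is accept/reject on amino-acid
changes, not a full codon rate matrix: relative codon frequencies, CpG
effects and among-site rate variation are not emulated, so passing recovery
tests demonstrates estimator correctness under the stated model, not
robustness to real genomes' heterogeneity.

**SNP panels** (`simulate_snp_panel`). Segregating sites are drawn as
Poisson($\theta L a_n$), $a_n = \sum_{i<n} 1/i$, placed at distinct
positions, each with derived-allele count $\propto 1/i$ (the neutral SFS)
or at a fixed frequency; carriers are assigned uniformly. `truth_pi` is the
realized mean pairwise difference per site of the emitted panel — its
expectation is θ, and the per-site π estimator recovers it *exactly*
because both are computed from the same emitted counts (their agreement is
an identity check on the bookkeeping; the independent check is the
all-pairs enumeration oracle). No linkage, recombination, demography or
sequencing error is simulated — π is insensitive to linkage, which keeps
the generator minimal, but panels are unrealistic for haplotype-based
statistics (out of scope here).

**Planted genomes** (`plant_paralog_genome`). Paralog pairs are laid out
with exact requested intergenic gaps (50 kb spacers between pairs), with
the answer key recorded under the strict `< 2500 bp` rule, including the
boundary cases 2499/2500/2501.

## Numerical and design choices

* All genomic coordinates are 1-based inclusive end-to-end (GFF3/VCF
  convention); interval queries compose exactly over disjoint covers.
* Degenerate inputs error early and specifically: zero 4D sites, zero
  comparable columns, `S = 0`, `L ≤ 0`, `n < 2` at a site, empty tandem
  set, `S2 = S0`.
* Saturation is a flagged state (4DTv) or an error (NG86), never silently
  truncated.
* Codon-pair tables are built once per session from the standard genetic
  code and cached; no alternative genetic codes.
* Test and validation cohort sizes — 200 replicates of 3,000 codons for
  divergence recovery, panels of n = 100 accessions over 10 kb for π, 50
  planted pairs for tandem detection — were chosen to make Monte-Carlo
  standard errors comfortably smaller than the assertion bands while a
  full run stays in the tens of seconds on a laptop.
* Seeds: simulators take an explicit `seed` and are byte-reproducible under
  it; pipeline manifests record the seed and parameters.

## Known limitations

* NG86 is the classical counting estimator; maximum-likelihood codon
  models (GY94-style), rate variation and alternative corrections for the
  4DTv distance are not implemented (one alternative can be plugged into
  `fourDTv()`).
* The tandem rule is distance-only; no synteny or tree reconciliation.
* The VCF reader targets plain-text, SnpEff-annotated VCF 4.x with GT
  fields and one interval per query; BCF and tabix random access are out
  of scope.
* Protein alignment quality is the caller's responsibility for deeply
  diverged pairs; threading faithfully propagates a bad protein alignment.
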