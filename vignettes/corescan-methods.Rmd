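---
title: "corescan: statistical model and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corescan: statistical model and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corescan)
```

This vignette documents the scoring model, the defaults and the numerical
conventions used by corescan, along with the reasoning behind each choice and
the limits of what the package can claim. It is the reference for anyone who
needs to know *why* the code does what it does, not just *how* to call it.

## 1. The scoring model

### 1.1 GC-normalized log2-likelihood scores

A motif of length $L$ is a position weight matrix (PWM) $P$ with
$P(i,j)$ the probability of base $i \in \{A, C, G, T\}$ at column
$j = 1, \dots, L$, each column summing to 1. Scores are log-likelihood
ratios against a background that depends only on the GC fraction $g$ of the
sequence set being scanned:

$$
p_G = p_C = \frac{g}{2}, \qquad p_A = p_T = \frac{1 - g}{2},
$$

$$
\operatorname{score}(i, j) \;=\; \log_2 \frac{\tilde P(i, j)}{p_i},
\qquad
\tilde P \;=\; \frac{P + c}{1 + 4c},
$$

where $c$ is a pseudocount (default $10^{-3}$) that regularizes zero entries
so the logarithm is finite; the denominator renormalizes the columns. A
window's score is the sum of the per-column scores of its bases; the maximal
attainable score is the sum of the column maxima. A window is reported as a
hit when its score reaches the element's cutoff.

Normalizing by the dataset's own GC content means a G/C-rich motif is not
rewarded merely for sitting in an AT-rich genome: the score measures
enrichment over what the local base composition would produce by chance. The
same motif scanned at two GC settings yields different scores by design;
`auto` GC estimation (pooled $(G{+}C)/(A{+}C{+}G{+}T)$ over all records, N
excluded) is the recommended default for whole-dataset work.

### 1.2 Handling of N and masked bases

`N` is treated pessimistically: it contributes the *minimum* of its column's
scores. An unknown base therefore never helps a window across the cutoff,
only genuine sequence evidence can. The alternative — averaging over the four
bases — would let long stretches of N accumulate middling scores and produce
phantom hits in masked regions. Lower-case (soft-masked) input is uppercased
by default; passing `mask_lower = TRUE` to the readers converts it to N
instead, inheriting the pessimistic rule.

### 1.3 Strands and coordinates

Both strands are scanned by default (the motif is scored against the reverse
complement; minus-strand hits are mapped back to plus-strand coordinates).
Positions relative to the TSS use the skip-zero convention standard in
promoter biology: the TSS base is $+1$, the base before it $-1$, and there is
no position 0. `tss_relative()` / `tss_absolute()` implement the two
directions and are exact inverses. For minus-strand hits the reported
TSS-relative start is the hit's 5'-most base on its own strand, so a motif
"starting at $-2$" means the same thing biologically on either strand.

## 2. The element library

### 2.1 Matrices

Fourteen elements are bundled: TATA, Inr, dInr, BBCA+1BW, DPE, MTE, BREu,
BREd, TCT, dTCT, Bridge, PB, Motif1 and GAGA. Their matrices are
reconstructed from published IUPAC consensus strings rather than copied from
a numeric source: each consensus letter admits a set of bases; disallowed
bases receive probability 0.02 per column and the allowed bases share the
remainder equally, rounded to 6 decimals by largest remainder so columns sum
exactly to 1. This makes the matrices fully reproducible from the one-line
consensus definitions in `tools/make_builtin_pwms.R` and keeps the package
free of data whose precision we could not verify. The cost is that the
bundled matrices are *consensus approximations*: they preserve which bases
are tolerated where, but not empirical base frequencies. Users with curated
frequency matrices should load them with `read_pwm()` — user matrices are
first-class citizens everywhere the built-ins are accepted.

### 2.2 Cutoffs

Each bundled element's default cutoff is 60% of its maximal score under a
neutral background (GC 0.5). A fraction-of-maximum rule keeps cutoffs
comparable across motifs of very different lengths and information content;
60% is permissive enough that single-base deviations from the consensus
usually still pass, and strict enough that random sequence rarely does.
Cutoffs are stored per element and can be overridden per run
(`cutoff_overrides` in `scan_pipeline()`, `--cutoffs` on the command line);
they are starting points, not calibrated significance thresholds, and no
p-value semantics are claimed.

### 2.3 Composite rules and the anchor axis

Downstream elements are only meaningful at a constrained distance from an
initiator's A+1 base. Each PWM carries an `anchor_offset` giving the column
of its reference base (A+1 for initiators); the bundled rules are:

| dependent | anchor | spacing window (anchor axis) |
|---|---|---|
| DPE | dInr or Inr | +28 .. +33 |
| MTE | dInr or Inr | +18 .. +22 |
| Bridge | dInr or Inr | +18 .. +33 |

Spacing is measured on the same skip-zero axis with the anchor's A+1 as
reference, so a DPE whose first base sits 27 bp 3' of A+1 has spacing +28.
The DPE window's lower edge corresponds to the canonical "+28 relative to
A+1" arrangement. When several anchors qualify for one dependent hit, exactly
one call is made, chosen by: highest anchor score, then spacing closest to
the window midpoint, then the smaller anchor position. Dependent hits with no
qualifying anchor are *kept and flagged* as orphans rather than deleted —
deleting them would silently conflate "no motif" with "motif without
context", which are different biological findings. Rules are data
(`rules.yaml`), not code: users can redefine windows or add dependencies
without touching the scanner.

## 3. TSS-dataset quality control

The QC module summarizes where an element's hits fall. For each occupied
position it reports the hit count, the fraction of that element's hits (in
percent, denominated by the element's own total so fractions sum to 100), and
both the mean and the median score — the median is robust to the long right
tail that high-scoring consensus matches create, the mean is the familiar
summary; reporting both costs nothing and avoids an arbitrary choice.

Two axes are available: `tss` (motif start relative to the TSS) and `anchor`
(composite spacing relative to the realized A+1; orphans are excluded since
they have no spacing). The per-element summary adds the modal position, the
modal fraction, and the *concentration*: the share of hits within ±2 of the
mode. Sharp concentration at the canonical position indicates precisely
mapped TSSs; smearing indicates positional noise. `compare_qc()` ranks
datasets per element by concentration, which is how two TSS datasets for the
same genome can be appraised against each other.

A numerical convention worth stating: when several positions tie for the
maximal count, the modal position is the lower median of the tied positions.
A perfectly uniform distribution over 20 contiguous positions therefore
reports a central mode and a ±2 concentration of 5/20 = 25%, which is the
honest answer for a distribution with no real mode.

## 4. The synthetic promoter generator

`generate_promoters()` builds i.i.d. background sequence at a chosen GC
fraction and plants motif instances per a list of `plant_spec()`s: each spec
has a target position (on the `tss` or `anchor` axis), a planting
probability, a Gaussian positional jitter (`round(rnorm(1, 0, sd))`, i.e. a
discrete Gaussian), and either the consensus sequence or an instance sampled
column-wise from the PWM. Anchor-axis plants are placed relative to the
*realized* position of the named anchor element in that sequence (falling
back to the TSS if the anchor was not planted), so jittered initiators drag
their downstream elements with them, as they should. Later specs overwrite
earlier ones where they overlap; overlapped plants are flagged in the truth
table rather than silently repaired. Plants that would extend outside the
sequence are skipped and counted. The seed is mandatory, the RNG state is
saved and restored, and the full truth table (target vs realized position,
planted instance, overlap flag) is returned — the generator is the package's
ground-truth instrument, so determinism and honesty about what was actually
planted matter more than realism.

What the generator does *not* emulate: dinucleotide or higher-order sequence
composition, nucleosome-driven periodicity, correlated occurrence of elements
across promoter classes, and TSS mapping artifacts other than plain Gaussian
positional jitter. Conclusions drawn from it are about the *detector*
(does scanning + QC recover what was planted?), not about biology.

## 5. Reproducibility and testing posture

All stochastic entry points require explicit seeds. The command-line `scan`
and `qc` paths are deterministic: re-running on the same input produces
byte-identical output files, which the test suite asserts. The test suite
validates the scanner against an independent brute-force oracle, checks the
closed-form score identity at GC 0.5, checks strand invariance
(reverse-complementing the input mirrors the hit set exactly), and verifies
end-to-end recovery of planted elements, composite spacings and QC
discrimination between jitter-free and jittered datasets. The tests assert
properties of the implementation on synthetic ground truth only; they do not
assert any empirical result from any external dataset, because no such
dataset ships with the package.

## 6. Known limitations

- The bundled PWMs are consensus-derived approximations (section 2.1), so
  absolute scores should not be compared against scores from
  frequency-derived matrices of the same elements.
- Cutoffs have no significance calibration; users needing FDR control should
  calibrate against shuffled or simulated background themselves (the
  generator is suitable for this).
- The zero-order background model ignores dinucleotide bias; CpG-related
  composition effects in particular are absorbed only through the global GC
  fraction.
- Composite calling is pairwise (one dependent, one anchor); higher-order
  arrangements (e.g. TATA + Inr + DPE jointly) are not modeled beyond what
  the per-pair calls imply.
- QC statistics are descriptive. Concentration differences between datasets
  are reported and ranked but not tested for significance.
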