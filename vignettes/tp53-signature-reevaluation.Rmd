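---
title: "Re-evaluating expression signatures that proxy TP53 status"
author: "TP53proxy maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-evaluating expression signatures that proxy TP53 status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TP53proxy)
```

## The problem

TP53-MDM2 inhibitors (e.g. NVP-CGM097, NVP-CFC218) block the degradation of
p53 by MDM2 and can therefore only act in cells with functional, wild-type
(WT) TP53. Not every WT line responds, so expression signatures built from
TP53 transcriptional target genes have been proposed to select responders.
The catch: a signature trained on sensitive-versus-insensitive lines
*without conditioning on TP53 status* can achieve apparently good validation
performance simply by re-detecting TP53-inactivated lines — which are
insensitive for mechanistic reasons — rather than by discriminating
responders among genuinely WT lines. Such a signature is a *proxy* for TP53
status.

TP53proxy packages the re-analysis workflow that exposes this failure mode:

1. a **multi-evidence TP53 status caller** over mutation class,
   copy-number (CN) ratio and mRNA expression;
2. a **filter-then-re-evaluate engine** computing confusion-matrix
   diagnostics before and after removing inactivated lines, with
   borderline-removal scenarios;
3. a **synthetic cohort generator** under which the proxy argument becomes
   a provable property rather than an anecdote.

## The status-calling model

TP53 can be inactivated through several mechanisms, so evidence is
combined by three independent rules, each with its own channel:

* **R1 (mutation)** — any TP53 mutation whose parsed class is in the
  inactivating set. The default set is every non-silent coding/splice class
  (`missense`, `nonsense`, `frameshift`, `inframe_indel`, `splice`); the
  policy is a `TP53Thresholds()` parameter so stricter readings (e.g.
  truncating-only) are expressible. Classes are parsed deterministically
  from HGVS p.-notation (`parseProteinChange()`), with anything unparseable
  falling through to `other` — never an error.
* **R2 (mRNA loss)** — TP53 mRNA strictly below 32, in MAS5-150 units
  (probe 201746_at). The strictness matters: a value of exactly 32 is
  *not* loss, and a line at 33 sits in the borderline zone (below).
* **R3 (bi-allelic DNA loss)** — CN ratio strictly below 0.25
  (1.0 = diploid).

A line is **inactivated** iff at least one rule fires; otherwise it is
**likely_wt**. Two further outcomes annotate but never flip a call:

* *allelic loss* (0.25 ≤ CN < 0.6): one WT allele can suffice for
  p53 function, so hemizygous loss alone is reported, not called. No line
  in the shipped 12-line evidence cohort is called on hemizygous loss
  alone, which is consistent with that choice.
* *borderline mRNA* (`[32, 32 + margin)`, default margin 8): marks
  expression just above the loss cutoff. The margin was chosen so a value
  of 33 is flagged while unambiguous WT values (≥ 40) are not; it is a
  reporting device only, echoed into every report header.

Frameshift or nonsense mutations co-occurring with mRNA loss are annotated
`nmd_likely`: premature-termination transcripts are degraded by
nonsense-mediated decay, so the two observations corroborate each other.

A missing channel (NA) skips its rule and is noted in the per-line trail; a
line with all three channels missing is uncallable and raises an error
naming the line. Read counts are stored as given and never gate a call —
a 7/1 alternative/reference observation still counts as a mutation call.

## Expression units

All cutoffs are defined on the "MAS5-150" scale: probe-set summaries
rescaled per sample so the 2% trimmed mean equals 150. `trimmedMean()`
drops `floor(n * f)` order statistics from *each* tail (the most common
reading of a two-sided trim; whether the convention trims 2% per tail or
in total is not fixed anywhere authoritative, so `trimFraction` is a
parameter and the other reading is one flag away). `scaleToTarget()` is
idempotent, invariant to positive rescaling of its input and
rank-preserving per sample — all asserted as properties in the test suite.
Probe-set summarization itself (e.g. Tukey-biweight over probe pairs) is
out of scope; inputs are assumed already summarized, and the module exists
mainly so synthetic data live on the correct scale.

## Signature evaluation

`confusionMetrics()` treats *observed sensitive* as the positive class and
*predicted sensitive* as test-positive — the only assignment under which
all five published fractions of the 40-line evaluation
(24/27, 2/13, 24/35, 2/5, 27/40) are reproduced simultaneously.
Zero-denominator metrics are `NA` ("undefined"), never an exception.
Lines with a missing prediction or observation for the compound are
excluded with a logged message, never silently.

`evaluateSignature()` emits three scenarios: all lines; the likely-WT
subset (after `filterLikelyWT()`); and the likely-WT subset minus
borderline-flagged lines. On the shipped validation cohort the last
scenario is exactly the DAN-G-removal footnote: specificity drops from
2/13 to 1/12 and NPV from 2/5 to 1/4, illustrating how fragile the
apparently non-zero specificity is. The package reports exact fractions
alongside 3-decimal values and leaves the judgment of whether PPV (0.686)
"differs" from the response rate (0.675) to the reader — no formal test is
performed, and none is claimed.

```{r example}
cohort <- sd1SyntheticValidation()
calls <- callCohort(cohort)
scen <- evaluateSignature(cohort, calls, "NVP-CGM097")
metrics(scen$likely_wt)
```

## The synthetic cohort generator

`generateCohort()` draws cohorts with the structure the argument assumes:

* latent status Bernoulli(`fracInactivated`), default 12/52 — the observed
  contamination rate of the validation set;
* inactivated lines receive exactly one mechanism (mutation : mRNA loss :
  CN loss mixed 9:2:1 by default, loosely shaped on the evidence table's
  composition — illustrative, not inferential) and are always observed
  insensitive (the mechanistic premise);
* mutation lines draw a protein change from templates spanning all
  inactivating classes, with Poisson read counts; frameshift lines lose
  expression with probability 0.5 (the NMD path, rate arbitrary and
  configurable);
* intact-mRNA expression is log-normal (`meanlog = log(250)`,
  `sdlog = 0.6`, spanning the few-hundred MAS5-150 range of expressed
  lines); mRNA-loss lines draw Uniform(0, 25), below the cutoff by
  construction;
* CN is Normal(1, 0.2) truncated at 0 for non-CN-loss lines,
  Uniform(0, 0.25) otherwise;
* true-WT lines respond with `wtResponseRate` (default 0.675, the
  published WT response rate), and the signature prediction matches latent
  status with `signatureConcordance`, else is flipped.

Substream seeds are derived once from the global seed, one per line, so a
line's draws never depend on cohort size or insertion order, and identical
config + seed reproduce the cohort exactly. The generator restores the
caller's RNG state on exit.

The **proxy-PPV property** then holds by construction and is asserted in
the tests: with perfect concordance, every true-WT line is predicted
sensitive, so among true-WT lines PPV is just the empirical response rate —
at n = 20 000 it lies within ±0.02 of 0.675. A signature can look
excellent cohort-wide and still carry *zero* information within the WT
stratum. Conversely the all-lines scenario shows inflated specificity
driven entirely by inactivated lines, the qualitative phenomenon the
filter-then-re-evaluate workflow exposes.

What the generator does **not** emulate: the 13 signature genes' actual
expression values (the signature is consumed as a binary prediction, as in
the validation tables), copy-number segmentation, batch effects,
mutation-call errors, or any correlation between expression noise and
response. Passing tests therefore demonstrate the logical structure of the
argument and the correctness of the machinery — not that any particular
real signature behaves this way.

## Synthetic stand-ins for the supplementary sets

The per-line supplementary sets behind the published 40-line and 113-line
evaluations are not printed in full anywhere this package can ship from,
but their margins are: the confusion counts (tp = 24, fn = 3, fp = 11,
tn = 2), the identity of the two true negatives (DAN-G, with mRNA 33, and
HCC-95), the 29/113 inactivated split and the 43/84 responders.
`sd1SyntheticValidation()` and `sd1SyntheticCfc218()` build deterministic
cohorts realizing those margins exactly; they are named and documented as
synthetic, and only lines the source names are named. Every quantity the
tests assert about them is a function of the margins, which is why the
stand-ins are sufficient.

## Numerical and design choices

* Strict inequalities at every cutoff, as the conventions are stated.
* Trim count `floor(n * f)` per side; ties keep order-statistic position.
* Cell-line names are joined after canonicalization (uppercase; spaces,
  hyphens, underscores stripped) because multi-omic tables disagree on
  punctuation; original spellings are preserved in output.
* Missing CN or expression is treated as unknown (rule skipped, logged),
  never imputed to a diploid/expressed default.
* Whether a line with CN < 0.25 but normal expression should be called
  inactivated is not testable from the shipped evidence rows (no such
  line exists there); R3 implements the natural reading of "bi-allelic
  loss" and calls it.
* A missense variant such as p.P27L counts as inactivating under the
  default class policy; the policy reproduces the published call without
  endorsing it, and a stricter set is one argument away.
* Reports are byte-stable (sorted keys, fixed 3-decimal floats) and echo
  every threshold in force, so that a report is interpretable without the
  config that produced it — status-calling disputes are precisely about
  silent criteria.

Problem sizes in the test suite were chosen to make binomial standard
errors small relative to the asserted tolerances: 20 000 lines for the
proxy-PPV property (SE ≈ 0.004 against a ±0.02 band), 10 000 for caller
recovery, 200 seeds for the tally-oracle equivalence.

## Limitations

The caller is a deterministic filter, not a classifier with calibrated
error rates: it inherits whatever false negatives the upstream mutation
calling has (the re-analysis itself hypothesizes one such line, HCC-95).
Functional impact of individual missense variants, germline/somatic
distinction and allele-specific CN are out of scope. The evaluation module
deliberately offers no ROC/AUC — the predictions are binary — and no
significance test comparing PPV to response rate.
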