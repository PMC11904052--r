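---
title: "Measuring linguistic distancing and abstractness: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linguistic distancing and abstractness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingdist)
```

## The two measures

This package quantifies two properties of free-text responses collected in
emotion-regulation experiments.

**Linguistic distancing** captures how far language stands from the "here
and now". Per trial we compute the percentage of word tokens in five
categories: first-person singular pronouns (*I, me, my*), present-tense
verbs, discrepancy words (*would, could, should*), articles (*the, a,
an*), and words with more than six letters (at least 7 alphabetic
characters). The five percentages are z-scored across all trials of a
study sample, the first three are reverse-coded (more "I"/present/
discrepancy language means psychologically *closer* language), and the
five z-scores are averaged into a single composite. Higher values mean
greater separation from the self and the present moment.

**Linguistic abstractness** follows the linguistic category model (LCM),
which orders word classes by abstraction: descriptive action verbs
(level 1, *walks*), interpretive action verbs (level 2, *help*), state
verbs (level 3, *admire*), adjectives (level 4, *charming*), and nouns
(level 5, *athlete*). A text's score is the weighted mean level over all
classified words,

$$\mathrm{abstractness} = \frac{1\,n_1 + 2\,n_2 + 3\,n_3 + 4\,n_4 + 5\,n_5}
{n_1 + n_2 + n_3 + n_4 + n_5},$$

ranging from 1 to 5. Integer weights 1-5 are the standard LCM convention
and are adopted here; texts with no classified words are flagged
non-qualifying and score `NA` (never 0). The qualifying threshold
defaults to one classified word and is configurable.

## The tagger and its lexicons

Commercial dictionary tools are not redistributable, so the package ships
open, versioned lexicons (plain text under `inst/extdata/lexicons/`, one
lowercase entry per line with a header naming the category and match
mode) and a deterministic rule-based tagger:

* closed classes (pronouns, articles, determiners, prepositions,
  conjunctions, adverbs, modals) are list lookups;
* verbs are recognised through an irregular-form table plus suffix rules
  (-s/-es, -ed, -ing with e-restoration and consonant undoubling) keyed
  to the LCM verb lists; verbs absent from all three lists fall to the
  documented default of level 2, the middle action class;
* adjectives and nouns are list lookups; unknown open-class words default
  to noun, the most abstract class — a deliberate bias that keeps novel
  content words scoreable;
* contracted forms are split (`I'm` becomes `I` + `'m`), and clitic verbs
  count as present-tense by default (`clitic_present = FALSE` switches to
  the stricter convention, since dictionary tools differ on this point).

Two context rules matter for the scores. First, *be* and *have* are
auxiliaries (excluded from LCM counting) when they govern a nearby
gerund or participle, and main verbs otherwise; copular *be* ("this *is*
terrible") is counted as a state verb, the prototypical state. Second,
tense is resolved in context: gerunds and participles inherit the tense
of their auxiliary ("am writing" is present, "was writing" past),
infinitives after *to* and modal-governed bases are tense-neutral, and
imperative bases count as present.

### Calibration on the matched-passage fixture

The package's only fully in-package scored anchor is a pair of passages
matched in content but maximally different in linguistic distance (first
person + present tense versus third person + past tense). Both must
yield the identical abstractness score 2.8125 = 45/16: sixteen
classified words whose levels sum to 45, invariant under the
pronoun/tense swap. The shipped verb lexicon is calibrated to this
fixture: *want*, *see* and *scare* sit in the interpretive-action list
(level 2) rather than the state-verb list, and copular *be* contributes
as a state verb as described above. These are defensible but not unique
classifications — LCM coding manuals disagree on perception and volition
verbs — and the calibration is exposed openly in the lexicon files; the
fixture is part of the test suite, and a pronoun/tense-swap property
test verifies that the calibration keeps distancing manipulations
score-neutral on arbitrary generated texts, which is precisely the
non-circularity property the two measures need.

## Aggregation and delta scores

Trial scores are averaged per participant and condition (abstractness
over qualifying trials; distancing over trials with at least one word).
For the three-condition reappraisal design, delta scores are reappraise
minus look-negative for language, look-negative minus reappraise for
affect (reappraisal success), and look-negative minus look-neutral
affect for emotional reactivity. For the distance-by-domain design,
language deltas are far minus close and the affect delta close minus
far, so positive values always mean "the manipulation moved the measure
in the expected direction".

Z-scoring uses the sample (n-1) standard deviation, the conventional
choice. The default z-scoring population is all trials within one study
sample, with original and replication halves standardized separately —
consistent with treating the sample as a covariate downstream; pooled
standardization is available via `z_group = NULL`. A category with zero
variance in its population maps to all-zero z-scores so constant-category
corpora never produce non-finite composites. Cronbach's alpha for the
composite is computed at trial level on the five reverse-coded z items;
the aggregation level is a genuine free choice and trial level is the
finest available.

## The inferential layer

Regressions standardize the response and all continuous predictors to
unit sample SD before an ordinary least-squares fit, so slopes are
standardized betas; the sample indicator enters as an unstandardized
factor covariate, and 95% intervals use the t distribution on the
residual degrees of freedom.

Repeated-measures ANCOVA uses the classical univariate decomposition:
participant enters as a blocking factor and the condition effect is the
type III drop-term F against the within-subject residual. Sum-to-zero
contrasts are mandatory — type III marginal tests are ill-defined under
treatment coding. A between-subject covariate is constant within
participants and therefore absorbed by the participant factor in the
within stratum; in the mixed 2 (distance, within) x 3 (domain, between)
analysis, the domain main effect is tested in the between-subject
stratum on participant means adjusted for the covariate, which spends
one denominator degree of freedom on the covariate. The
distance-by-domain interaction is tested in the within stratum with a
properly sum-coded interaction block.

Effect sizes are partial eta squared,
$\eta_p^2 = F\,df_1/(F\,df_1 + df_2)$, with 90% confidence limits
obtained by inverting the noncentral-F CDF for the noncentrality
parameter at the 5% tails (bisection, tolerance 1e-8 on the CDF scale)
and mapping through $\lambda/(\lambda + df_1 + df_2 + 1)$; 90% rather
than 95% because the F test is one-sided. The lower limit clips to zero
when the observed F falls below the central critical value — a known
boundary property of noncentral inversion, which also means the interval
covers a *true* zero effect about 95% of the time while coverage at
interior effect sizes is exactly the nominal 90%; the coverage test
therefore uses a known nonzero effect. Reported values are rounded half
away from zero to 2 decimals.

Within-subject error bars subtract each participant's mean, add back the
grand mean, compute per-condition t intervals on the normalized scores,
and widen half-widths by $\sqrt{C/(C-1)}$ for $C$ conditions.

## What the generator emulates — and what it does not

The synthetic generator assembles each trial's text from template word
pools drawn from the packaged lexicons, sampling one category per word
slot (first-person pronoun, other pronoun, article, discrepancy word,
present-tense verb, past-tense verb, adjective, noun, or neutral
filler) at configured per-condition emission rates. Pool words are
chosen to be context-unambiguous, so the category membership and LCM
level of every emitted word is known by construction and the scorer can
be tested for *exact* agreement with the generator's bookkeeping — the
point of a template-pool design over naturalistic generation.

Defaults mirror the two study designs: 217 participants with 20 trials
in each of three within-subject conditions, and 464 participants split
over three between-subject domains with 20 close and 20 far trials.
Far/reappraise conditions emit more nouns, adjectives and long words
(higher abstractness), the social-far condition suppresses 95% of
first-person emission, and the temporal-far condition only moves
present-tense emission to past tense — reproducing the construction
that tense shifts alone leave abstractness flat. Emission rates were
chosen once to give abstractness means near 3.4-3.7 on the 1-5 scale
and plausible category percentages; they aim to mirror the direction
and rough size of condition differences, not to fabricate empirical
effect sizes.

Affect is a discretized latent normal: condition mean plus a participant
random effect (SD 0.8) plus trial noise (SD 0.6), rounded and clipped to
the 1-7 scale. The rating process behind real scales is unmodeled and
this latent-normal choice is a stand-in, labeled as such. The linkage
coefficients `lambda_dist` and `lambda_abs` couple a participant's
realized (z-scored) language shift to their affect shift, so the
generating correlation is known; because measured affect adds trial
noise and discretization on top of the latent success term, recovered
standardized betas are mildly attenuated relative to the configured
lambda (about 5% at the default noise levels), which is visible and
intentional — it is exactly the attenuation a real experiment faces.

One structural difference from real data is worth naming: the generator
draws word categories independently within a trial, so the five
composite items are essentially uncorrelated across synthetic trials and
Cronbach's alpha of the composite hovers near zero, whereas real writing
styles induce the moderate item correlations seen in practice. Alpha on
synthetic data therefore tests the arithmetic, not realistic
reliability.

Passing tests on this generator demonstrate that the pipeline recovers
structure it was designed to emit: real free text has spelling errors,
syntax the rule tagger will occasionally misread (possessive *'s*,
prepositional *like*), and vocabulary outside the lexicons (which
defaults to noun). None of those behaviors is exercised by the
generator, so test results bound implementation correctness, not
field validity of the measures.

## Problem sizes used in the checks

The test suite runs entirely on synthetic data built at test time:
emission-rate recovery uses ~10,000 trials (tolerance 0.01 absolute);
the effect-size interval coverage check uses 2,000 simulated
24-participant datasets with a known interior effect (expected coverage
90%, asserted within +/-3.4%); linkage recovery uses 200 replicate
datasets of 200 participants with 6 trials per condition at
`lambda_abs = 0.4`, requiring the configured value inside the estimated
95% interval in at least 90% of replicates. These sizes were chosen as
the smallest designs whose sampling error is well inside the asserted
tolerances.

## Known limitations

* The tagger is rule-based and dictionary-driven: it has no syntactic
  parser, tags *like* as a state verb even in prepositional use, reads
  `'s` as a contracted *is*, and cannot disambiguate noun/verb homographs
  outside its lists.
* The LCM verb lexicon is small and calibrated to the matched-passage
  fixture; scores on open-domain text will differ from proprietary
  dictionary pipelines in absolute level (directional contrasts are the
  supported use).
* The repeated-measures machinery expects complete condition sets; the
  pipeline drops participants with missing conditions (logged) rather
  than imputing.
* English only; no sentiment analysis; no multilevel trial-level models —
  analyses operate on participant-level condition means.
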