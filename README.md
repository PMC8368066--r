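# seminfer

Can the meaning contrast between **causative** verbs (*break*, *open*,
*kill* — an agent makes a patient change state) and **non-causatives**
(*think*, *go*, *want*) be inferred from nothing but word co-occurrence —
no syntax, not even word order? And does the answer differ between
child-directed speech (short, repetitive, nominal-dense) and adult
conversation or written language (long, lexically and constructionally
varied)?

`seminfer` is an R package for computational psycholinguists who want to
ask that question quantitatively: it implements the full pipeline from
annotated corpora to Bayesian inference, plus a genre-parameterized
synthetic corpus generator so every stage is testable without access to any
proprietary corpus.

## What it computes

1. **Embeddings.** A from-scratch, bit-deterministic skip-gram
   negative-sampling (SGNS) trainer (Rcpp) with order-dissolved contexts:
   for each center word *w* and context word *c* within a symmetric window
   of 1–6 tokens, it maximizes

   `log σ(u_c · v_w) + Σ_k log σ(−u_nk · v_w)`,

   with negatives drawn from the unigram^0.75 distribution. Utterances are
   bracketed by `^^` and `$$` markers so one-word utterances still carry
   signal. Training layers add word-class tags or minimal dependency
   subtrees (a head plus its direct dependents) to the raw lemma stream.

2. **Discrimination.** Pairwise cosine distances
   `d(i,j) = 1 − cos(θ_ij) ∈ [0, 2]` between all causatives and
   non-causatives (23 × 9 = 207 pairs at full vocabulary coverage), minus a
   chance baseline: the mean distance of random pairs of frequent verbs
   (≥ 10 verb-tagged occurrences). Positive "above-baseline" scores mean
   the meaning classes are better separated than chance.

3. **Inference.** Hierarchical Bayesian regressions
   `score ~ genre + (1 + genre | caus) + (1 + genre | noncaus)` (Study 1)
   and the analogous `~ layer` model (Study 2), with Student-t(5) priors
   (scale 10 intercept / 2.5 coefficients), crossed per-verb random
   intercepts and slopes, HPD intervals, tail probabilities, and
   PSIS-LOO / Pseudo-BMA+ model weights. Plus neighbor-joining clustering
   of embedding distances and bootstrap probes of verbal constructions
   (nominal proportion, nominal entropy, construction entropy).

## Worked example

Generate contrasting synthetic corpora, run Study 1 at window 1, and read
off the genre effect (reduced dimension/epochs for speed; package defaults
are dim 200, 100 epochs):

```r
library(seminfer)

cds <- generate_corpus(preset("cds_like"),  n_sessions = 20,
                       utterances_per_session = 150, seed = 101)$corpus
ads <- generate_corpus(preset("ads_like"),  n_sessions = 20,
                       utterances_per_session = 47,  seed = 102)$corpus
cds
#> <sem_corpus> genre=cds_like | 20 session(s), 3000 utterance(s), 11150 token(s)

cfg <- pipeline_config(windows = 1, dim = 32, epochs = 12,
                       n_baseline_pairs = 2000, chains = 2,
                       iter = 400, warmup = 400, seed = 1)
res <- run_study1(list(cds = cds, ads = ads), cfg)

res$baselines[["1"]]
#> <baseline_estimate> mean 0.1440 (sd 0.1514) over 2000 pairs of 45 verbs

summarize_posterior(res$fits[["1"]], masses = 0.90)
#>          term   mean hpd_lo_90 hpd_hi_90 prob_above_zero rhat ess
#> 1 (Intercept)  0.265     0.264     0.267               1    1 261
#> 2    genreads -0.249    -0.251    -0.248               0    1 305
```

Reading: in the child-directed-like corpus, causative/non-causative pairs
sit on average 0.265 cosine-distance units *above* the random-verb baseline
(the intercept; the entire posterior is above zero), while the adult-like
corpus loses essentially all of that separation (genre coefficient −0.249,
entirely below zero) — raw co-occurrence suffices in CDS-like input but not
in adult-like input. The distributional probes say why:

```r
bootstrap_probe(cds, 1, "construction_entropy", seed = 1)
#> <probe_result> construction_entropy | genre=cds_like window=1: 2.4853 (bootstrap sd 0.0313)
```

Verbs in the CDS-like corpus inhabit few, repetitive word-class frames
(low entropy, high nominal density); the same probe on the adult-like
corpus gives systematically higher entropies and fewer nominals.

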