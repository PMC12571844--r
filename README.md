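# ohcmatch

Dual-channel neural matching of patients and physicians in online health
Q&A communities.

## The problem

On a health Q&A platform, a patient posts a consultation request — a short
title, a longer description, structured profile fields and semantic tags —
and several physicians answer; the patient may *adopt* (endorse) one
answer. Routing each request to physicians likely to produce an adopted
answer is an expert-recommendation problem with two awkward features:
the signal lives on both sides (query semantics *and* physician expertise,
both stated credentials and what they actually answer), and a long tail of
low-activity physicians has almost no interaction history to learn from.

`ohcmatch` is for researchers studying this kind of matching model: it
implements the full architecture, a seeded synthetic community to exercise
it on (real platform corpora of this kind are not redistributable), and
the evaluation suite — classification, top-K ranking, and a popularity-bias
audit over head/middle/tail physician tiers.

## The model

Two independent channels meet at a scoring head:

* **Patient channel** — title, content, profile and tag token sequences
  each pass through embedding → width-3 windowed convolution with ReLU
  (`c_i = relu(W_c ·[W_{i-1}; W_i; W_{i+1}] + b_c)`, zero-padded at the
  boundaries) → tanh-scored softmax attention pooling
  (`a_i ∝ exp(tanh(v·c_i + v_b))`, `e_w = Σ a_i c_i`). The four pooled
  vectors are projected to the 128-dim patient representation
  `e = [e_w, e_t, e_z, e_r]`.
* **Physician channel** — credentials are encoded by the same field
  pipeline into `r_s`; the replies of the recent 15-day window are each
  encoded and run through a bidirectional GRU whose aligned directional
  states are averaged per step, then reduced by scaled tanh-score
  attention into the temporal vector `r_d`; `r = [r_s, r_d]` (128-dim).
* **Scoring head** — `score = sigmoid(Ψ_FC([e, r]) + e·r)`: a 4-layer FC
  stack (256 → 128 → 64 → 32 → 1) over the concatenated pair plus the
  bilinear inner product of the two representations.

Training: binary cross-entropy under Adam, batch 256, learning rate 0.01,
at most 4 epochs with early stopping on validation AUC, dropout 0.5.
Cold-start: physicians with < 5 replies get a credential-keyed surrogate
temporal vector (averages over warm physicians with the same specialty /
title rank / hospital tier); sparse queries are expanded through a
pluggable synonym lexicon. The methods vignette
(`vignettes/matching-model.Rmd`) documents every formula, default and
design choice.

## Worked example

```r
library(ohcmatch)

cfg   <- generator_config(n_interactions = 1500, signal_strength = 0.8, seed = 7)
gen   <- generate_corpus(cfg)
print(gen$corpus)
#> <ohc_corpus> 800 queries, 200 physicians, 1500 interactions (46.3% positive)

split <- split_dataset(gen$corpus$interactions, gen$corpus$physicians, seed = 7)
model <- train_matcher(gen$corpus, split, ohc_config(), seed = 7, verbose = TRUE)
#> epoch 1: loss 0.6966, val ACC 0.5533, val AUC 0.6143
#> epoch 2: loss 0.6881, val ACC 0.5867, val AUC 0.6486
#> epoch 3: loss 0.6756, val ACC 0.6633, val AUC 0.7484
#> epoch 4: loss 0.6240, val ACC 0.8033, val AUC 0.8430

report <- evaluate_model(model, gen$corpus, split$test, seed = 7)
print(report)
#> <metric_report>
#>  split   n  acc    auc precision_at_k recall_at_k ndcg_at_k
#>   cold   0   NA     NA             NA          NA        NA
#>   warm 300 0.83 0.8566        0.07521      0.6895    0.3285
#>    all 300 0.83 0.8566        0.07521      0.6895    0.3285
#> per-tier bias audit:
#>    tier exposure_rate recall_at_k coverage_contribution
#>    head        0.0641      0.5556               0.09574
#>  middle        0.4051      0.6071               0.39362
#>    tail        0.5308      0.7655               0.51064
```

What the numbers mean: the generator plants 4 latent specialties and
labels pairs by Bernoulli draws — adoption probability 0.85 when query and
physician share a specialty, 0.10 otherwise — so even a perfect model
cannot exceed an AUC of ≈ 0.88 at this signal strength; test AUC 0.86
means the planted structure is essentially recovered. Precision@10 is low
by construction (each query has ~1 relevant physician among 50
candidates), while Recall@10 = 0.69 says the adopted physician lands in
the top 10 of 50 for most queries. The bias audit shows top-10 slots and
distinct recommendations spread across the activity tiers roughly in
proportion to tier sizes (10/40/50%). In this run no test interaction
involved a cold physician, so the cold row is empty.

A command-line front end (`inst/cli/ohcmatch.R`) wraps the same functions:
`generate`, `train`, `recommend` (TSV of rank/physician/score),
`evaluate`, `bias-report`.

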