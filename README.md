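# framescore

Public-health researchers and computational social scientists studying how
news media frame suicide deaths need a reproducible way to measure subtle,
attitude-laden language — stigmatizing ("shallow", "pathetic", "immoral"),
glorifying ("understandable", "brave", "motivated"), or isolating
("unhappy", "depressed", "sad") — and to ask whether that framing differs
by the decedent's gender and by the circumstance attributed to the death.
`framescore` implements that analysis as a tested R pipeline.

## What it computes

Each attitude frame is represented by a lexicon: a handful of validated
seed descriptors, expanded through a pluggable synonym source and pruned by
two coders' keep/remove decisions. The frame's centroid vector is the
unweighted mean of its term embeddings,

    v_f = (1/|L_f|) * sum over t in L_f of e(t),

and each decedent's text is embedded sentence by sentence, the article
vector being the mean of its sentence vectors. The framing score is the
cosine similarity

    s(d, f) = cos(a_d, v_f) = (a_d . v_f) / (|a_d| |v_f|)  in [-1, 1].

Scores are then compared across gender with two-sided Mann–Whitney U tests
(exact permutation null for small untied samples, tie- and
continuity-corrected normal approximation otherwise), and across
circumstances of suicide with a plug-in mutual information estimator
I(G; S) in bits, computed from shared equal-width bins over the pooled
scores. Cohen's κ quantifies annotator agreement, and a circumstance ×
gender summary table reports counts with half-up one-decimal percentages.

The embedding backend is pluggable. The built-in backend is a deterministic
feature-hashing embedder (each token maps to a seeded signed one-hot unit
vector), so the entire pipeline runs offline and reproducibly; a contextual
transformer backend can be supplied through the same one-method contract.
A synthetic-corpus generator produces annotated corpora with known injected
frame-language rates per (gender, circumstance, frame) cell, so every
statistical claim is testable against ground truth.

## Worked example

```r
library(framescore)

# a synthetic corpus: 100 decedents per gender, stigma terms injected at
# 15% of tokens for male decedents and 5% for female decedents
backend <- hash_backend(seed = 101)
rates <- tibble::tibble(gender = c("cis_male", "cis_female"),
                        circumstance = "*", frame = "stigma",
                        rate = c(0.15, 0.05))
spec <- synthetic_spec(n_male = 100, n_female = 100,
                       injection_rates = rates, seed = 1001)
gen <- generate_corpus(spec)

victims <- tibble::tibble(victim_id = gen$annotations$victim_id,
                          gender = gen$annotations$gender,
                          circumstances = gen$annotations$circumstances,
                          text = gen$articles$text)
centroids <- frame_vectors(default_lexicons(), backend)
scores <- score_corpus(victims, centroids, backend)

s <- scores[scores$frame == "stigma", ]
mann_whitney(s$score[s$gender == "cis_male"],
             s$score[s$gender == "cis_female"],
             labels = c("cis_male", "cis_female"))
#> # A tibble: 1 x 9
#>   group_a  group_b      n_a   n_b mean_a mean_b     U        p method
#>   <chr>    <chr>      <int> <int>  <dbl>  <dbl> <dbl>    <dbl> <chr>
#> 1 cis_male cis_female   100   100  0.625  0.245  9957 9.27e-34 normal_approx
```

Male-decedent articles score far higher against the stigma centroid
(mean cosine 0.63 vs 0.25) and the rank test detects the injected
difference decisively — the generator planted a 3× difference in stigma
token rates, and the pipeline recovers it. An un-injected frame shows no
systematic difference. `stratified_mi()` localises such differences by
circumstance, and `run_pipeline()` executes the whole chain from JSONL
corpus to score/comparison/MI/table artefacts; a thin command-line front
end lives at `inst/cli/framescore.R` with subcommands `synth`, `filter`,
`score`, `compare`, `mi`, `table1` and `run`.

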