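# triagerec

Symptom-based department triage and doctor recommendation for outpatient
appointment platforms.

Online registration platforms face two linked problems: patients often do
not know which hospital department fits their symptoms, and once triaged
they must pick a doctor with almost no signal. `triagerec` implements a
two-stage hybrid recommender for both:

1. **Content-based triage.** Tokenized chief complaints become TF-IDF
   vectors over a symptom vocabulary
   (`W_ji = (n_ij / n_*j) · ln(N/D_i + 1)`); each department's profile
   pools its patients' complaints *weighted by their post-visit ratings*
   (`TF_i = Σ_k n_ik r_k / Σ_k n_*k r_k`), so visits that turned out well
   describe the department more strongly than historical mis-triages.
   A new patient goes to the department with the highest mean-centered
   (adjusted) cosine similarity.
2. **Clustered collaborative filtering.** Each department's historical
   patients are clustered offline with a trust-weighted K-means — the
   distance `D_uv = T_uv · √Σ_{i∈I(u,v)} (W_ui − W_vi)²` with trust
   multiplier `T_uv = √|I(u) ∪ I(v)| / |I(u) ∩ I(v)|` over symptom sets —
   with k chosen at the elbow of the SSE curve. At query time the target's
   `m` most similar cluster members form a sparse patient×doctor rating
   matrix that is densified by explicit-feedback ALS, and
   `r̃_ai = r̄_i + Σ_j sim(a,j)(r̃_ji − r̄_j) / Σ_j sim(a,j)` scores every
   doctor; the top N are returned. Restricting the neighbor search to the
   assigned cluster shrinks the candidate set several-fold at essentially
   unchanged precision/recall — the point of the clustering stage.

A reproducible synthetic clinic generator, a precision/recall evaluation
harness, and the standalone numerics of a registration-review pipeline
(multi-scale 1-D convolution, wave-function eigenvalue correction,
softmax head) round out the package. The methods vignette
(`vignettes/triagerec-methods.Rmd`) documents every model, parameter and
numerical choice.

## Worked example

```r
library(triagerec)

clinic <- generate_clinic(clinic_config(n_patients = 300, seed = 42))
corpus <- symptom_corpus(clinic$visits)

# stage 1: triage every complaint and score it against the planted truth
tri <- triage(corpus, top = 1)
triage_accuracy(tri, clinic$truth)
#> [1] 1

# stage 2: fit the full model and recommend doctors for one complaint
model <- clinic_model(clinic$visits, clinic$ratings, k = 4, seed = 42)
target <- clinic$visits$tokens[[7]]    # s0092x3 s0096x4 s0097x1 s0185x1
rec <- recommend(model, target, seed = 42)
rec
#> # A tibble: 5 × 3
#>    rank doctor_id score
#>   <int> <chr>     <dbl>
#> 1     1 doc0022    5
#> 2     2 doc0019    4.88
#> 3     3 doc0017    4.31
#> 4     4 doc0023    3.46
#> 5     5 doc0021    3.17
attr(rec, "department_id"); attr(rec, "candidate_set_size")
#> [1] "3"
#> [1] 16
```

The complaint triages into department 3 and lands in one of its patient
clusters; only 16 cluster members (not the whole department) are searched
for neighbors, and the five listed doctors are ranked by their predicted
1–5 score (clipped for reporting, ranked unclipped).

The before/after-clustering experiment on the same clinic:

```r
report <- before_after_comparison(clinic, algorithms = "ALS_User_CF",
                                  seed = 42, k = 4)
glance(report)
#> # A tibble: 1 × 5
#>   mean_accuracy_gain mean_recall_gain candidates_before candidates_after n_test
#>                <dbl>            <dbl>             <dbl>            <dbl>  <int>
#> 1              0.714             1.79              48.6             12.1     56
```

Cluster-restricted search scans 12 candidates instead of 49 per patient
while precision\@5 and recall\@5 move by well under a tenth — clustering
buys speed, not accuracy loss.

## File formats

Visits use a line-record text format, one visit per line (`true_dept` is
optional):

```
patient:p00001 true_dept:3 dept:3 doctor:doc0023 rating:5 tokens:s0035x1,s0093x6
patient:p00002 true_dept:2 dept:2 doctor:doc0011 rating:5 tokens:s0072x1,s0076x2
patient:p00003 true_dept:1 dept:1 doctor:doc0002 rating:4 tokens:s0011x2,s0024x1
```

Ratings are `patient,doctor,rating` CSV triples (`write_ratings()` /
`read_ratings()`), with sparse MatrixMarket export via
`write_rating_mtx()`. Profiles serialize to JSON
(`{"vocabulary": [...], "weights": {...}}`).

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript inst/cli/triagerec.R generate --patients 500 --seed 1 --out data
Rscript inst/cli/triagerec.R triage --corpus data/corpus.txt --input new.txt --top 3 --out triage.csv
Rscript inst/cli/triagerec.R cluster --corpus data/corpus.txt --dept 1 --k-range 2:15 --out model.json
Rscript inst/cli/triagerec.R evaluate --seed 1 --out run1
```

Exit codes: 0 ok, 2 configuration error, 3 data error, 4 numeric failure.

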