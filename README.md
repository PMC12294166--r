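# bbsnet

Few-shot image grading for perishable food, built around three ideas:

1. **A lightweight attention-augmented backbone.** A ShuffleNetV2-style
   convolutional feature extractor in which every normalization layer is
   *batch channel normalization* (BCN) — a learnable blend of batch-wise
   and channel-wise standardization,

   $$Y=\gamma\left[\iota\frac{x-\mu_1}{\sqrt{\sigma_1^2+\epsilon}}+(1-\iota)\frac{x-\mu_2}{\sqrt{\sigma_2^2+\epsilon}}\right]+\beta$$

   — and whose units embed *bi-level routing attention* (BRA) blocks:
   token attention restricted to the top-k most affine of an S×S grid of
   spatial regions (defaults S = 7, stage top-k 7/8/16/49).
2. **A cosine-prototype episodic classifier.** For a k-way n-shot episode
   the class prototypes $\mu_1,\dots,\mu_k$ are the unit-normalized means
   of the support features, and a query $q$ is classified by
   $p=\mathrm{softmax}(M\hat q)$, whose logits are the cosine similarities
   $\cos\theta(q,\mu_c)$. Direction carries class identity (hue, texture);
   magnitude carries nuisance luster, which cosine ignores.
3. **Transductive fine-tuning.** Per episode, a softmax head initialized
   at $W=M$, $b=0$ is trained on the frozen features with support
   cross-entropy plus entropy regularization of the unlabeled query
   predictions, sharpening decision boundaries from a handful of labels.

Grades are anchored in microbial load: five freshness grades spanning
storage times 0–96 h (representative counts 4.2×10³–5.4×10⁶ CFU/g) with
the fresh limit at 10⁶ CFU/g.

The intended users are researchers in food-quality imaging and few-shot
learning who want a transparent, fully testable CPU implementation: every
layer (convolutions, BCN, routed attention, the MLPs) carries a
hand-written analytic backward pass verified against finite differences,
so the whole pipeline trains without any deep-learning framework. Since
the original graded-pork photographs are not publicly deposited, the
package ships a synthetic generator that reproduces the statistical
structure the method assumes — grade-dependent hue drift, grade-independent
multiplicative luster jitter, local texture noise — plus feature-space
episodes with controllable directional separation.

## Worked example

```r
library(bbsnet)

# microbial grading ---------------------------------------------------------
grade_from_colony_count(c(4.168e3, 5e5, 1.778279e6))
#> [1] "First-grade fresh pork"  "Third-grade fresh pork"
#> [3] "First-grade spoiled pork"

# a 5-way 5-shot feature episode with moderate noise ------------------------
ep <- generate_feature_episode(k = 5, n = 5, q = 15, dim = 64,
                               angle_sep = pi/2, mag_jitter_sd = 0.3,
                               noise_sd = 0.18, seed = 7)
evaluate_episode(ep)$accuracy          # cosine-prototype classifier
#> [1] 0.9866667

ft <- finetune(ep, cfg = finetune_config())
ft$accuracy                            # after transductive fine-tuning
#> [1] 1
head(ft$trace, 3)                      # support CE + query entropy descend
#>   epoch       ce  entropy    total
#> 1     0 1.277108 22.00233 23.27943
#> 2     1 1.253034 21.53494 22.78798
#> 3     2 1.229314 21.07764 22.30696

macro_metrics(confusion_counts(ep$query$labels, ft$predicted, 5))
#> macro Acc 1.0000 | Sen 1.0000 | Spe 1.0000 | Pre 1.0000 (overall 1.0000)
```

The episodic accuracy is the fraction of the 75 query items assigned to
their true grade; the fine-tuning trace shows the transductive objective
(summed support cross-entropy plus query-prediction entropy) decreasing
from its prototype initialization; the macro metrics are the unweighted
means of the per-class one-vs-rest accuracy, sensitivity, specificity and
precision.

The image pipeline runs the same way from the shell via the thin CLI in
`inst/cli/bbsnet`:

```sh
bbsnet generate-data --seed 1 --out data/
bbsnet pretrain      --seed 1 --data data/ --out ckpt.rds
bbsnet finetune-eval --seed 1 --data data/ --checkpoint ckpt.rds --out eval/
```

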