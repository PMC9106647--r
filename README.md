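# anchortm

Distributional anchor regression with transformation models: robust
distributional prediction for continuous, censored and ordinal responses
under anchor-induced distribution shift.

## The problem

Prediction models fail when test data do not follow the training
distribution. When the heterogeneity is driven by exogenous *anchor*
variables `A` (environments, centers, exogenous continuous factors) that
may influence the response `Y`, the covariates `X` and hidden confounders
`H`, one can trade a little in-distribution accuracy for robustness
against shift perturbations in the direction of the anchors. For the
linear model this is anchor regression: minimize

    || (I - Pi_A)(y - X b) ||^2 / n  +  gamma * || Pi_A (y - X b) ||^2 / n

with `Pi_A` the orthogonal projector onto the anchor columns; `gamma = 1`
is OLS, `gamma = 0` partials the anchors out, `gamma -> Inf` approaches
two-stage least squares.

`anchortm` generalizes this to *distributional* regression via
transformation models. The conditional distribution is

    F(y | x) = F_Z( h(y | x) ),      h(y | x) = b(y)' theta - x' beta

with a fixed inverse link `F_Z` (standard normal, standard logistic, or
minimum extreme value) and a monotone baseline transformation `b(y)'
theta` (linear, Bernstein polynomial of order `P`, or ordinal
thresholds). The likelihood handles exact, left-, right- and
interval-censored data as well as ordinal classes. Least-squares
residuals are replaced by *score residuals* — the derivative of each
observation's log-likelihood with respect to an artificially added
intercept — which reduce to scaled least-squares residuals in the normal
linear model and to (signed) martingale residuals under the minimum
extreme value link. The model is estimated by minimizing the
distributional anchor loss

    L(theta, beta) = - sum_i l_i / n  +  xi * || Pi_A r ||^2 / n,

where `r` is the score-residual vector and `xi >= 0` controls the causal
regularization. `xi = 0` is the maximum-likelihood estimate; `xi -> Inf`
drives the correlation between anchors and score residuals to zero, which
makes the first conditional moment of the residuals invariant under
do-interventions on the anchors ("diluted causality"). For the normal
linear model the loss is equivalent to linear L2 anchor regression with
`xi = (gamma - 1) / 2`.

The package also ships the structural-equation simulator used to study
these estimators (scenario presets `la`, `nla`, `iv1`, `iv2` with do- and
push-interventions), evaluation protocols (per-observation negative
log-likelihood, worst-case NLL quantile curves, absolute prediction error
at the conditional median, leave-one-environment-out cross-validation)
and a plain-text command-line interface.

## Worked example

Train on heterogeneous data from the linear anchor scenario, evaluate on
test data whose anchors were pushed to three times their training spread:

```r
library(anchortm)
cfg   <- scenario_preset("la")
train <- simulate_scenario(cfg, n = 300, seed = 1)
shift <- apply_intervention(cfg, "push", list(kind = "normal", mean = 0, sd = 3))
test  <- simulate_scenario(shift, n = 2000, seed = 2)

design <- anchor_design(train$A)
basis  <- linear_basis(default_support(train$y))
mle    <- fit_anchor_tm(train$response, train$X, design, xi = 0,
                        link = "probit", basis = basis)
anchor <- fit_anchor_tm(train$response, train$X, design, xi = 6,
                        link = "probit", basis = basis, start = mle$par)
anchor
#> anchor_tm_fit: xi = 6, mean NLL 1.4846, penalty 0.001064, converged
#> max |anchor-residual corr|: 0.00948
#> transformation model: probit link, linear basis
#> theta: 0.02773 0.9354
#> beta:  0.1305 1.122 1.099 0.1799 0.2545 0.01991 -0.01543 0.01996 -0.03172 0.0187

round(rbind(
  mle    = nll_quantiles(nll_contributions(mle,    test$response, test$X)),
  anchor = nll_quantiles(nll_contributions(anchor, test$response, test$X))), 3)
#>        q0.05  q0.5  q0.9 q0.95     q1
#> mle    0.977 1.281 2.689 3.381 10.174
#> anchor 0.987 1.241 2.389 3.016  7.274
```

The regularized model (`xi = 6`, the equivalent of `gamma = 13`) pays a
small premium on the easy observations (the 5% quantile of the
per-observation negative log-likelihood rises from 0.977 to 0.987) and is
markedly better where it hurts: the 95% quantile drops from 3.38 to 3.02
and the worst case from 10.2 to 7.3. The fitted shift coefficients
(`beta`, on the latent standard-normal scale) concentrate on the two
truly causal covariates (2 and 3).

The same interface runs from the shell:

```sh
Rscript -e 'anchortm::anchortm_cli()' simulate --scenario la --n 300 --seed 1 --out tr
Rscript -e 'anchortm::anchortm_cli()' fit --data tr.csv \
  --response-cols y_lower,y_upper --censoring-col cens \
  --covariates x1,x2,x3,x4,x5,x6,x7,x8,x9,x10 --anchors a1,a2 \
  --link probit --basis linear --gamma 13 --out fit1
Rscript -e 'anchortm::anchortm_cli()' evaluate --data tr.csv \
  --response-cols y_lower,y_upper --censoring-col cens \
  --covariates x1,x2,x3,x4,x5,x6,x7,x8,x9,x10 \
  --model fit1_manifest.json --out eval1
```

## Package layout

- `R/basis.R` — linear / Bernstein / ordinal response bases, monotone
  log-increment reparametrization.
- `R/links.R` — probit, logit and minimum-extreme-value inverse links
  with log-scale tail computations.
- `R/tm.R`, `R/fit.R` — censored/ordinal likelihood, score and martingale
  residuals, maximum likelihood, distributional prediction.
- `R/anchor.R` — anchor design and projection, closed-form linear L2
  anchor regression, the distributional anchor loss, regularization
  paths.
- `R/sem.R` — structural-equation simulator and scenario presets.
- `R/evaluation.R` — NLL quantile curves, APE, leave-one-environment-out
  cross-validation.
- `R/cli.R`, `R/io.R` — command-line interface, delimited-text data and
  JSON manifests.

See `vignettes/anchor-transformation-models.Rmd` for the methods account
(model, assumptions, numerical choices, simulator design, limitations).
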