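# dpps

Geometric modelling of defensive peripersonal space (DPPS) from hand-blink
reflex (HBR) data.

## The problem

When a threatening stimulus approaches the face, the blink elicited by
electrical stimulation of the wrist grows stronger. `dpps` implements a
geometric account of that enhancement: the nervous system is modelled as
tracking the probability that a threat at location **r** would *hit* a
defended body area, and scaling the defensive reflex with that probability.
A threat is a point launching a straight hitting action in a random
direction (independent unit-variance Gaussian components); gravity shifts
the vertical component's mean by −c_grav. The hit probability is the
(direction-weighted) fractional solid angle of the defended solid,

    P(r) = Ω(r) / 4π,

estimated by Monte-Carlo ray casting (2 million trajectories by default),
and the predicted reflex magnitude is linear in it:

    S(r) = a · P(c_grav, r) + b.

Candidate defended areas are clipped ellipsoids: the whole head
(semiaxes 9.8 × 7.4 × 11.3 cm), the face (its forward half), the upper face
(forward-upper quarter), and the two eyes (small half-ellipsoids,
0.5 × 2 × 2 cm). Fitting (a, b, c_grav) per geometry by χ² minimization
against normalized per-position HBR means — and comparing goodness-of-fit
across geometries — asks which body representation best explains the
spatial map of defensive excitability. The DPPS for any response cutoff S₀
is the region where S > S₀.

The package is for sensorimotor/peripersonal-space researchers who want to
fit these models to their own trial-level reflex data, and for
methodologists who want a fully testable, simulation-backed implementation:
a synthetic study generator reproduces the statistical structure of the
six-experiment hand-position design (26 conditions), so every stage is
validated by parameter-recovery rather than by unavailable raw recordings.

## Worked example

Simulate a six-experiment study from a known ground truth (face geometry,
a = 1, c_grav = 1.05), normalize it, and compare the four geometries:

```r
library(dpps)

layout  <- layout_positions()
config  <- generative_config(seed = 7, ray_seed = 7, n_rays = 1e5)
trials  <- generate_study(config, layout)          # 6,240 trial records
dataset <- normalize_dataset(trials, layout)       # 26 positions, mean ± SEM
cmp     <- compare_models(dataset, fit_config(n_rays = 1e5, seed = 7))
cmp
#> <dpps_comparison> ranked by GoF (best first)
#>   geometry       gof      p_value   c_grav accepted
#>       face 0.3998706 9.860192e-01 1.115662     TRUE
#>  half_face 0.8247158 6.656738e-01 0.250000     TRUE
#>       head 2.4233021 8.751012e-04 1.531215    FALSE
#>       eyes 5.5842177 7.660841e-13 1.600000    FALSE
```

The generating geometry (face) ranks first (χ²/dof ≈ 0.40, P = 0.99:
accepted) with c_grav recovered near its true 1.05; the head and eyes
geometries are rejected at P < 0.05, while the half-face — a subset of the
face whose predictions differ mainly below eye level — survives at this
single-study noise level. `tidy(cmp)` returns the
ranked table as a tibble, `glance(cmp)` the one-row summary, and
`autoplot(cmp)` / `autoplot(cmp$fits$face)` the comparison and
observed-vs-predicted plots. From the best fit, the DPPS field and region:

```r
fit   <- cmp$fits$face
field <- response_field(field_grid(step = 2),
                        response_params(fit$a, fit$b, fit$c_grav),
                        defended_area("face"),
                        trajectory_model(n_rays = 1e5, seed = 7))
autoplot(dpps_region(field, cutoff = 0.1))   # sagittal slice of the bubble
```

A command-line wrapper over the same functions lives at `inst/cli/dpps.R`
(`simulate`, `normalize`, `fit`, `compare`, `field`, `demo` subcommands).

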