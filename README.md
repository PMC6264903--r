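# gainfieldnet

`gainfieldnet` is a rate-based simulator of a self-organising neural
network that learns to transform eye-centred (retinotopic) visual
representations into head-centred representations.  It is aimed at
computational neuroscientists studying coordinate transformations in the
primate dorsal visual pathway: the package implements gain-modulated input
populations, a competitive output layer, a family of biologically local
trace / anti-Hebbian learning rules, the saccade-and-fixation training
protocol that drives self-organisation, a manually prewired reference
network, and the correlation-based reference-frame analysis used to
classify output neurons.

## The model in brief

A visual target at head-centred location *h* seen with eye position *e*
lands at retinal location *r = h − e*.  Input neurons are retinotopic with
eye-position gain fields, either peaked

&nbsp;&nbsp;&nbsp;&nbsp;*v* = exp(−‖e−β‖²/2ρ²) · exp(−‖r−α‖²/2σ²)

or monotonic (sigmoidal)

&nbsp;&nbsp;&nbsp;&nbsp;*v* = [1+exp(κ(e−β))]⁻¹ · exp(−‖r−α‖²/2σ²).

Output neurons integrate their sparse afferent drive through a leaky
activation τ_h dh/dt = −h + Σ w v, compete through a population-percentile
threshold inside a logistic rate function, and carry a low-pass memory
trace τ_q dq/dt = −q + v.  During training the synapses follow a trace
learning rule (dw/dt = ϱ q v in the standard form, with delayed-trace and
anti-Hebbian variants) with each weight vector renormalised to unit length
after every update.  Because natural gaze keeps a target fixed in
head-centred space across many eye movements, the trace binds input
patterns sharing *h* onto the same output neurons — with peaked gain fields
the output layer becomes predominantly head-centred; with monotonic gain
fields the standard rule fails and the modified rules are needed.

Each tested neuron gets an E×T response matrix over E = 4 eye positions
and T = 80 head-centred targets; its head-centredness Π (mean pairwise
row correlation) and eye-centredness Ω (the same on retinally aligned
windowed rows) classify it as head-centred (Π > 0 and Π > Ω), eye-centred
(Ω > 0 and Ω > Π), or unclassified.

## Worked example

Experiments are packaged as recipes.  The reduced scale keeps the full
12,261-neuron peaked input population and the complete training/testing
protocols, shrinking only the output layer (200 neurons) and the epoch
count (5); it runs in a few seconds.  Full scale
(`gf_recipe("peaked_standard", "full")`: 900 outputs, 20 epochs) takes a
few minutes:

```r
library(gainfieldnet)

run <- run_recipe(gf_recipe("peaked_standard", "reduced"), seed = 1)
glance(run)
#> # A tibble: 2 × 7
#>   phase     epoch n_neurons n_head_centred head_centred_rate
#>   <chr>     <int>     <int>          <int>             <dbl>
#> 1 untrained     0       200             41             0.205
#> 2 trained       5       200             79             0.395
#>   mean_head_centredness mean_eye_centredness
#>                   <dbl>                <dbl>
#> 1                 0.156                0.146
#> 2                 0.303                0.208
```

Before training, 20.5% of the randomly weighted output neurons happen to
classify as head-centred with a weak mean head-centredness of 0.16; five
epochs of visually guided training with the standard trace rule raise the
head-centred fraction to 39.5% and the mean head-centredness among
head-centred neurons to 0.30 (at full scale, 20 epochs carry this to
roughly three quarters of the population).  `tidy(run)` returns the
per-neuron classification table; `autoplot(run$responses, neuron)` draws a
neuron's response curves per eye position, `plot_weight_map(run$model,
neuron)` its topographic synaptic weight structure (a diagonal band for
head-centred solutions, a horizontal band for eye-centred ones), and
`autoplot(run$classification)` the population Π/Ω scatter.

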