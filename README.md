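# dendsyn

Propagation of synchronous spiking in purely random networks with nonlinear
dendrites: an exact event-driven simulator plus the Markov-chain theory that
predicts when synchrony persists.

## The scientific problem

Precisely timed spike patterns are usually explained by embedded feed-forward
structures (synfire chains). `dendsyn` implements and analyzes an alternative
mechanism: **fast dendritic sodium spikes**. When several excitatory inputs
arrive at a dendrite within a sub-millisecond window, the somatic
depolarization is not the linear sum of the EPSPs but a supra-additively
amplified, saturating function of it. The package asks — and answers, both by
simulation and analytically — whether this single-cell nonlinearity lets
synchronous spiking propagate persistently through a network with *purely
random* (Erdős–Rényi) connectivity, where a conventional, additively coupled
network lets every synchronous pulse die out.

It is aimed at computational neuroscientists studying collective dynamics of
spiking networks, branching-process descriptions of neuronal avalanches, and
nonlinear dendritic integration.

## Model and theory in brief

Leaky integrate-and-fire neurons, `dV/dt = -γV + I_ext` between delta-pulse
synaptic inputs delivered after a common delay τ, threshold `V_Θ = 1`, reset
`V_r = 0`, supra-threshold drive. Synchronously arriving excitatory strengths
`x` are modulated by a piecewise-linear sigmoid σ(x): identity below `Θ_b`,
affine up to `Θ_s`, constant at `s_sat` beyond; inhibition adds linearly:
`λ = σ(Σε_e) + Σε_i`.

A synchronous group of `g` neurons recruits the next group one delay later.
With the `g` senders refractory and the rest equilibrated, each of the
`N − g` available neurons fires independently with probability

    p(g) = Σ_{m,l} P(m,l | g) · F(σ(m ε_e) + l ε_i),

where `(m,l)` is the trinomial number of excitatory/inhibitory links from
the group and `F` is the right-cumulative of the stationary
membrane-potential density (diffusion approximation with the Siegert
self-consistent rate, or measured semi-analytically). The next group size is
`Binomial(N − g, p(g))` with expectation `Ê(g) = (N − g)·p(g)`; fixed points
of `Ê` against the diagonal — ψ− (spontaneous level), ψ0 (initiation
threshold, unstable), ψ+ (propagation size, stable) — decide whether
synchrony propagates persistently.

## Worked example

```r
library(dendsyn)

fx <- reference_params("nonlinear_ref")   # calibrated N = 2000 fixture
fx$params
#> LIF network parameters
#>   N = 2000, p_conn = 0.05  (mean in-degree 100.0)
#>   p_exc = 0.8, p_inh = 0.2, eps_exc = 0.01, eps_inh = -0.035
#>   gamma = 1, I_ext = 1.25, V_theta = 1, V_reset = 0, tau = 0.1
#>   mean total input strengths: E_tot = 0.8, I_tot = -0.7

# analytical group-size map and its fixed points
tm <- transition_model(fx$params, fx$mod,
                       g = unique(round(c(0:10, seq(10, 2000, length.out = 120)))))
tm
#> Group-size transition model (N = 2000, density: diffusion, nu = 0.7338)
#>   p(g) on 130 group sizes; max E_hat = 295.8 at g = 194
#> Fixed points of the group-size map:
#>   g* =     0.00  stable (slope 0.225)
#>   g* =    54.43  unstable (slope 1.993)
#>   g* =   260.66  stable (slope -0.773)
#>   psi- = 0.00 < psi0 = 54.43 < psi+ = 260.66 (bistable)

# one full stimulated run: equilibrate, pulse 100 neurons, classify
tr <- run_trial(fx$params, fx$mod, g0 = 100, seed = 1)
tr$label
#> [1] "stable_propagation"
tr$chain
#> Synchrony chain: g0 = 100, 251 steps observed (horizon 251)
#>   sizes: 100 194 294 233 230 217 260 255 251 233 240 244 252 247 234 266 ...
```

Reading: the theory predicts bistability — pulses above ψ0 ≈ 54 neurons
ignite a persistent chain fluctuating around ψ+ ≈ 261 — and the event-driven
simulation confirms it: the chain initiated with 100 neurons settles near
240–260 synchronous spikes per delay step, far above the largest spontaneous
background pulse (11 neurons in this run). Replacing `fx$mod` with
`dendritic_modulation(linear = TRUE)` makes the same network's chains die
within a few steps, and `parameter_scan()` maps the coupling-strength region
where propagation is stable.

A command-line interface (`exec/dendsyn`) exposes `simulate`, `theory`,
`scan`, `calibrate` and `fixtures` subcommands over YAML/JSON configurations;
see the vignette for the methods behind each step.

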