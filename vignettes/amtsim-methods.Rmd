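---
title: "Modeling acupuncture and moxibustion treatment dynamics with amtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling acupuncture and moxibustion treatment dynamics with amtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amtsim)
```

## The model

amtsim simulates the organ-level dynamics that traditional Chinese
medicine (TCM) attributes to acupuncture and moxibustion treatment (AMT).
Each of the twelve internal organs — the five element-bearing viscera
(liver/wood, heart/fire, spleen/earth, lung/metal, kidney/water), the
pericardium, and the six bowels — carries a scalar state $f_V \in
[0.5, 5.5]$, with $[2.5, 3.5]$ read as the healthy band, lower values as
deficiency and higher values as excess. One simulation cycle
$\tau - 1 \to \tau$ applies seven stages in a fixed order, with the
intermediate stages conventionally written $\tau', \tau'', \tilde\tau,
\hat\tau$:

1. **Five-Elements stage** (synchronous over the five viscera):
   $f_X(\tau') = g\,f_{gen(X)}(\tau-1) - r\,f_{res(X)}(\tau-1) +
   s\,f_X(\tau-1)$, where $gen(X)$ is the viscus whose element generates
   $X$'s (wood→fire→earth→metal→water→wood) and $res(X)$ the one whose
   element restricts it (wood⊣earth, earth⊣water, water⊣fire, fire⊣metal,
   metal⊣wood). One widely reprinted prose gloss of this stage inverts the
   direction of generation; the package follows the update rule itself,
   which matches classical Five-Elements theory (the heart is generated by
   the liver and restricted by the kidney).
2. **Viscera → bowels**: $f_B(\tau') = c\,f_V(\tau') + s\,f_B(\tau-1)$
   for all six exterior–interior pairs, including
   pericardium–triple energizer.
3. **Bowels → viscera**: $f_V(\tau'') = c\,f_B(\tau') + s\,f_V(\tau')$.
4. **Acupoint stimulation** (below).
5. **Substance generation**: qi, blood and body fluid pools
   $f_i = f_i^{normal} \cdot B \cdot G_i$, where
   $B = [nh - |\sum_{j \in O} f_j - nh|]^+ / (nh)$ measures systemic
   balance over the organ set $O$ and
   $G_i = [h - |f_{me(i)} - h|]^+ / h$ the health of the substance's
   generator organ; negative factors floor at zero.
6. **Substance transport**: every organ receives
   $f_{i\_V} = (f_i / v)\, B\, U_i$ with $U_i$ the analogous health factor
   of the transporter organ — transport is uniform across organs.
7. **Absorption and clamping**:
   $f_V(\tau) = m f_V(\hat\tau) + q f_{q\_V} + b f_{b\_V} + l f_{l\_V}$,
   clamped once per cycle to $[0.5, 5.5]$.

The defaults are the published calibration: $g = 0.15$, $r = 0.05$,
$s = 0.9$, $c = 0.1$, $e = 0.25$, $w = 0.01$, $h = 3$, $v = 10$,
$m = 0.999$, $q = b = 0.004$, $l = 0.002$. Two identities make the
all-healthy state an exact fixed point: $g - r + s = 1$ and $c + s = 1$
keep every organ at $h$, and with $f_i^{normal} = 3$ the absorption stage
reconstitutes exactly: $3 \cdot 0.999 + 0.3 (q + b + l) = 3$. That
derivation is why `fi_normal` defaults to 3 — it is the unique value
closing the loop — and the fixed point is verified to $10^{-9}$ over 1000
cycles in the test suite.

The generator/transporter assignments default to standard TCM physiology:
the spleen (the source of acquired essence) generates all three
substances; qi is moved by the lung, blood by the heart, fluid by the
kidney. The organ set $O$ defaults to all twelve organs ($n = 12$). All
of these are `amt_params()` fields because the source calibration does
not pin them down.

## The stimulation stage

A protocol maps WHO-notation acupoints to integer levels $\mu \in
[-5, 5]$ (negative purgation, positive tonification, 0 untreated). Each
treated point contributes a stimulus potential $fp(\mu)$ to its
meridian's affiliated organ; contributions on one organ sum. Conception
vessel, governor vessel and extra points have no affiliated organ; by
default their potential is split equally across the five viscera
(`vessel_routing = "viscera"`), since protocols use them for systemic
regulation; `"none"` or a custom weight vector are available.

The functional form of the stimulation response is the one genuinely open
reconstruction choice in the package, and we document the reasoning in
full. The printed saturating form $fp = \mu e v / (v + e v) = 0.2\mu$,
applied additively with weight $w = 0.01$, changes an organ by at most
$0.01$ per cycle — two orders of magnitude below the intrinsic relaxation
of the organ network. Under that reading the reference Meniere's case
recovers on the network's own timescale (first full recovery at cycle 27)
and the treatment is epiphenomenal. Conversely, *any*
deviation-independent input strong enough to accelerate recovery
displaces the equilibrium: a constant per-cycle input $\delta$ shifts an
organ's resting state by roughly $\delta / (1 - \lambda) \approx
22\delta$ at the default persistence, so no constant-in-time stimulus can
simultaneously deliver recovery within eight cycles and stabilization
near 3.0 — the two behaviors the case study exhibits. The stimulation
must therefore act on the *disorder*, not on the level.

The default response is deviation-gated:
$$\Delta f_V = w \sum_{a \to V} fp(\mu_a) \cdot |f_V - h|, \qquad
  fp(\mu) = \mu e v.$$
Treatment is strong while the organ is disordered and fades as balance is
restored, which is also the clinical dose–response intuition: needling a
balanced organ at normal intensity maintains rather than distorts it.
Under this default the reference case reaches the healthy band at cycle
6 and settles near 3.0, and wrongly signed protocols misbehave in the
clinically expected way — purging an already deficient organ (as several
of the random screening rounds do) drives it to the floor, which is what
gives those rounds their near-zero in-range scores. Both choices are
plugged, not wired: `stimulus = "saturating"` restores the literal
quotient form, `response = "additive"` the ungated application, and
`stimulus` also accepts an arbitrary `function(mu, params)`.

Note one consequence of the gating: the effect of a level on a perfectly
balanced organ is exactly zero, so monotonicity of the first-cycle state
in $\mu$ holds strictly only for organs off the target — the property
tests use a deficient start.

## Execution as a colored Petri net

`amt_simulate()` runs the cycle in two interchangeable ways. The direct
mode evaluates the stage functions sequentially. The net mode
(`mode = "cpn"`) builds a colored Petri net in which every organ state,
substance pool, delivery channel and treated acupoint is a typed place
and every stage is a transition whose arc expressions *are* the stage
equations, written in a whitelisted arithmetic mini-language (constants,
variables, `+ - * /`, `abs`, `min`, `max`), so a serialized net is
self-contained and safe to re-load.

Left to itself such a net would fire stages in arbitrary interleavings.
The token-guided transition control (TGTC) layer compiles a
series–parallel schedule into control places, tokens and arcs: every
scheduled transition gains a control place and input control arc;
sequential steps hand the token on; a parallel block's opening transition
splits the token, one per branch, and the branches' terminal transitions
converge on a shared join place consumed with arc weight equal to the
branch count. When a parallel block follows another directly, a synthetic
control transition collects the joined token and re-splits it. Control
places are unit-colored and disjoint from the data layer; stripping them
restores the original net exactly, which the tests assert structurally.

The schedule for one physiological cycle is

```
seq( t_snapshot,
     par( seq(t_gen_liver,  t_vb_liver,  t_bv_liver),
          ...,                              # one chain per pair
          seq(t_vb_pericardium, t_bv_pericardium) ),
     t_stim, t_generate, t_transport, t_absorb )
```

The six viscus–bowel chains run concurrently — they are physiologically
independent — but the Five-Elements stage must read every viscus at
$\tau - 1$ while the chains rewrite those same places. The snapshot
transition resolves this: before the parallel block it copies each
viscus's generator and restrictor values into pair-local places, making
the chains genuinely non-interfering while keeping the stage synchronous.
Each cycle re-seeds the start place with one control token and runs the
net to a dead marking under the seeded random firing policy; because every
admissible interleaving computes the same marking (the chains commute),
direct and net execution agree to $10^{-9}$ per organ per cycle, which
the acceptance suite checks on the reference protocol and 100 generated
ones.

Engine-level numerical choices: bindings are enumerated over
deterministically sorted candidate tokens, so ties between tokens of
equal value break reproducibly; `cpn_run(seed = s)` is bitwise
reproducible; inhibitor arcs enable only on an *empty* place (the common
threshold-0 convention; the construction does not need any other);
markings are immutable-by-contract — `fire()` returns a fresh marking —
which is what makes trace storage and the brute-force oracle replays
cheap.

## Evaluation

A simulated protocol is scored on three components over cycles
$\tau = 1..T$ (the presenting pathology at $\tau = 0$ is not counted
against a treatment):

* **PTR** — mean over the twelve organs of the fraction of cycles spent
  inside $[2.5, 3.5]$;
* **fRMSD** — 1 iff every organ's minimum sliding-window RMSD from the
  target $h$ falls at or below a threshold (window $W = 10$ cycles,
  threshold $\theta = 0.5$): a sustained near-healthy episode for the
  worst organ;
* **PET** — the fraction of (organ, cycle) points inside the pointwise
  min/max envelope of the reference simulations, widened by a margin
  $\delta = 0.25$.

The composite is the fixed weighted sum
$\mathrm{Eval} = 0.4\,\mathrm{PTR} + 0.4\,\mathrm{fRMSD} +
0.2\,\mathrm{PET}$, reproduced against all sixteen printed screening
rows in the tests. The component-level constants $W$, $\theta$ and
$\delta$ are package defaults exposed in `evaluate_trajectory()` and the
`eval` block of run configurations: the source material specifies the
combination layer and the components' intent precisely, but not these
constants, so we chose conventional values (a window of a fifth of the
course; a threshold at the half-width of the healthy band; a margin of a
quarter of that half-width) and kept the combination layer insulated from
them. One printed screening row (C5) is internally inconsistent in the
published table — its envelope component must read 0.01, not 0.10, for
its printed composite 0.002 — and the shipped table records the
self-consistent value.

## The explorer as a synthetic-protocol generator

`generate_protocol()` draws protocols under the three screening
strategies: **R** samples uniformly from all 409 registry points minus
the reference protocol's points ("no overlap with known treatment" is
enforced at the acupoint level — the published random rounds share
meridians with the reference, only never points); **M** restricts to the
meridians of the affected organs (for the Meniere's pattern: LR, SP,
KI); **C** to the meridians of their paired bowels (GB, ST, BL).
Protocol sizes are uniform on 5–7 points (the range spanned by the
published rounds) and levels uniform on the nonzero integers in
$[-5, 5]$; the published rounds favor $\pm 3$ but state no generation
law, so we kept the distribution uninformative and the level set
configurable.

What these synthetic draws emulate is the *screening* situation: many
candidate point–level combinations, most of them clinically wrong,
scored against one validated reference. What they do not emulate is
real clinical variability — inter-patient parameter differences, course
interruption, point-location error or non-integer dosing. Passing the
screening tests therefore demonstrates that the pipeline discriminates
correctly *within the model's own dynamics*, not that the model's
rankings transfer to patients; the composite score has no empirically
calibrated cutoff, and we treat ranks, not absolute values, as the
meaningful output.

## Problem sizes and costs

The shipped checks run at the study's own scale: 50-cycle courses, the
16 fixture protocols, the 10-transition control-schedule example
(explored exhaustively: 20 interleavings), 100 protocol draws for the
direct-vs-net equivalence check and 1000 draws per strategy for the
constraint properties; the fixed-point check runs 1000 cycles. The net
mode executes roughly 23 firings per cycle and runs a 50-cycle course in
about two seconds; the direct mode is effectively instant. The
brute-force engines (`reachable_sequences()`, the binding enumerator)
carry explicit node budgets and error rather than run away.

## Known limitations

* The stimulation functional form is a documented reconstruction (see
  above), not a published equation; conclusions that hinge on stimulus
  *magnitude* rather than sign and target should be re-checked under the
  alternative forms.
* The eight extraordinary meridians beyond the conception and governor
  vessels are not modeled, matching the source system's own scope.
* The TGTC compiler covers series–parallel schedules only; arbitrary
  partial orders, priorities and preemption are out of scope.
* Substance generator/transporter assignments are fixed per substance;
  organ-specific transport efficiencies are not modeled (delivery is
  uniform by construction).
* Evaluation constants ($W$, $\theta$, $\delta$) shift component values
  when changed; comparisons are only meaningful within one setting.
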