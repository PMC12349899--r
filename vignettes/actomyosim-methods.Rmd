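---
title: "Model and methods: actomyosin force generation at the thick-filament level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`actomyosim` simulates disorganized actomyosin structures with three
coarse-grained elements, all built from cylindrical segments:

* **F-actin** — chains of 140-nm segments with structural polarity
  (vertex 0 is the barbed end). Extensional springs maintain the segment
  rest length; angular springs between consecutive segments maintain a
  straight equilibrium, with the bending stiffness set by the persistence
  length: $\kappa_{b,A} = L_p k_B T / r_{0,A}$ with $L_p = 9\,\mu m$.
  Discrete binding sites sit every 7 nm along each segment (20 per
  segment), shared by cross-linkers and motor arms.
* **Motors (myosin II thick filaments)** — a straight, stiff backbone of
  serially connected segments with a central arm-free *bare zone*; every
  endpoint of an arm-bearing segment carries two arms, and each arm lumps
  $N_h = 8$ myosin heads. Arms on the left half of the backbone walk
  toward the left backbone end and vice versa (bipolar polarity). A bound
  arm is a two-spring element: a transverse spring with equilibrium
  distance 13.5 nm between anchor and binding site, and a longitudinal
  spring (equilibrium 0) that penalizes axial slip of the binding site
  away from the foot of the perpendicular dropped from the anchor onto
  the filament axis.
* **Cross-linkers (ACPs)** — two 23.5-nm arms joined at a center bead by
  a soft hinge whose equilibrium is straight. Once both arms are bound
  the link is permanent.

Motion is overdamped Langevin dynamics: for each vertex,
$\mathbf{F}_i - \zeta_i \dot{\mathbf r}_i + \mathbf{F}_i^T = 0$,
integrated with the forward Euler scheme at $\Delta t = 1.15\times10^{-5}$ s.
The thermal force satisfies the fluctuation–dissipation relation
(component variance $2 k_B T \zeta_i / \Delta t$), and drags are the
approximate cylinder form $\zeta = 3\pi\mu r_c (3 + 2 r_0/r_c)/5$.
Volume exclusion acts between actin segments only, as a harmonic
repulsion of range $r_{c,A} = 7$ nm on the minimum segment–segment
distance.

### Motor mechanochemistry

Arm-level kinetics use three rate laws, calibrated to the three
observables that define myosin II behavior at this resolution:

* binding at $40 N_h\,s^{-1}$ to a free site within the capture radius
  ($r_{0,M2} + 2\times7$ nm), subject to two rules: the filament's
  barbed-end direction must have a positive projection on the arm's
  walking direction (heads cannot engage a misoriented filament), and two
  arms sharing a backbone endpoint may not bind the same filament;
* walking toward the barbed end in 7-nm site steps with the linear
  force–velocity law $k_w(F) = (v_0/7\,\text{nm}) \max(0, 1 - F/F_{st}N_h)$,
  giving an unloaded velocity $v_0 = 140$ nm/s and an arm stall force
  $F_{st} N_h = 45.6$ pN (5.7 pN per head);
* catch-bond unbinding $k_u(F) = k_{u0} e^{-F/F_{cat}}$ with
  $k_{u0} = 20\,s^{-1}$, $F_{cat} = 10$ pN, floored at $0.01 k_{u0}$.

The load $F$ is the component of the arm's spring force that opposes its
walking direction, floored at zero. The kinetics layer is a pluggable
strategy (`motor_kinetics()`); the default above stands in for a full
mechanochemical cycle model while reproducing its externally calibrated
observables exactly, which is what the bundle-scale questions probed here
depend on.

### Measurement

Tension is measured on cross-sections: every spring element crossing a
plane contributes the plane-normal component of the force it exerts on
its lower endpoint — positive in tension, negative in compression — and
contributions are bucketed into actin, cross-linker, motor-arm and
motor-backbone categories. Only extensional (spring) terms are summed.
$F_{tot}$ is the mean of the plane totals over planes and steady-state
frames (planes every 200 nm along z for bundles; 20 planes per axis
along x and y for networks). The maximal motor force is
$F_M^{max} = \tfrac12\sum_i F_{M,z}^i$ (bundles) or
$\tfrac14(\sum_i F_{M,x}^i + \sum_i F_{M,y}^i)$ (networks), where
$F_{M,\cdot}^i$ sums the magnitudes of motor $i$'s arm spring-force
components; the efficiency is $\eta = F_{tot}/F_M^{max}$.

Steady state is detected on the $F_{tot}$ time series: the earliest
suffix window of at least 20 frames whose fitted linear trend drifts by
less than 1% of the window mean over the window. When no suffix
qualifies the final half of the series is used and the result is
flagged; in practice the contractile runs below approach their plateau
asymptotically through slow arm exchange, so the flagged tail mean is a
faithful plateau estimate.

### Contractile-unit overlap theory

Permanent cross-linkers between two motors let the filament network
cancel one motor's force against the other's, partitioning a bundle into
serially connected contractile units. Two motors escape this
cancellation when their backbones overlap by at least the critical
length $L_c = 2 L_{sp}(N_a/4 - 1)$ — twice the arm-bearing length of one
backbone half. The effective number of cooperating motors is
$$\Xi = \max_{i,\,j \in \{L,R\}} \Big(1 + \sum_{k \neq i} \xi_{ik}^j\Big),
\qquad
\xi = \begin{cases} 1 & L_c \le L_{ov} \le L_M\\
L_{ov}/L_c & 0 < L_{ov} < L_c\\ 0 & L_{ov} = 0,\end{cases}$$
and the predicted bundle force is $F_{est} = F_{st} N_h N_a \Xi / 2$.
The side rule used for $j$: a neighbor counts on side L (R) of motor $i$
when its backbone center lies left (right) of $i$'s center, and on both
sides when its backbone spans $i$'s center. This membership rule is one
of several consistent readings of the side restriction; it is fixed,
documented, and verified against an exhaustive brute-force evaluation.
For 2D networks, motors are compared only when their (undirected) axes
differ by less than 30°, using overlaps of projections onto the pair's
mean axis.

## Parameter choices

Printed model constants: $\Delta t = 1.15\times10^{-5}$ s, segment
length 140 nm, cross-linker arm 23.5 nm, backbone segment 42 nm,
transverse arm equilibrium 13.5 nm, sites every 7 nm, binding at
$40 N_h\,s^{-1}$, $N_h = 8$, $F_{st} = 5.7$ pN, $v_0 = 140$ nm/s,
$L_p = 9\,\mu m$. The remaining constants are package defaults, chosen
once from physical scales and the stability of the explicit Euler
scheme, and all configurable:

| parameter | default | rationale |
|---|---|---|
| $\mu$ | 0.86 Pa s | cytoplasm-scale effective viscosity; at water viscosity no spring stiff enough to hold its rest length within thermal fluctuations is stable at the model's $\Delta t$ (stability requires $\kappa \Delta t/\zeta \lesssim 2$) |
| $\kappa_{s,A} = \kappa_{s,M1}$ | $10^{-2}$ N/m | thermal length fluctuation $\sqrt{k_BT/\kappa} \approx 0.6$ nm (0.5% of $r_0$); worst-mode stability ratio $\approx 1.1$ |
| $\kappa_{b,M}$ | $20 \kappa_{b,A}$ | backbone persistence length ~50 um; backbones stay straight |
| $\kappa_{s,ACP}$ | $2\times10^{-3}$ N/m | holds cross-links while adding little vertex stiffness |
| $\kappa_{b,ACP}$ | $5\times10^{-26}$ N m | soft hinge; initial bent placements relax without large prestress |
| $\kappa_{s,M2} = \kappa_{s,M3}$ | $10^{-3}$ N/m | 7 pN of load per 7-nm walking step: stall reached in ~7 steps |
| $\kappa_{r,A}$ | $1.69\times10^{-3}$ N/m | soft-core exclusion, max ~12 pN |
| $d_A$ | 7 nm | actin diameter (drag and repulsion cutoff) |
| $d_M$ | 120 nm | drag envelope of a backbone bead with its two 8-head arm bundles; also keeps the stiff backbone well inside the Euler stability margin |
| $k_{u0}$, $F_{cat}$ | 20 s$^{-1}$, 10 pN | low arm duty when free, strongly bound near stall |

Numerical choices: kinetic events are evaluated every 5 integration
steps with probabilities $1 - e^{-k \cdot 5\Delta t}$ (all $< 2\times
10^{-2}$; event-time quantization of $5.75\times10^{-5}$ s is far below
every kinetic timescale). The actin–actin neighbor list is kept on a
uniform cell grid and rebuilt every 12 steps with a 25-nm skin (typical
per-step displacements are below 2 nm). Thermal deviates come from a
counter-based generator seeded once per run from R's RNG stream, so
`set.seed()` makes whole trajectories bit-reproducible. A run aborts with a diagnostic if any per-step displacement
exceeds half a segment length, which signals a mis-configured
stiffness/time-step combination rather than physics. Bending forces use
the exact analytic gradient of $\tfrac12\kappa_b\theta^2$; the gradient
magnitude is bounded for all angles, and only at the degenerate folded
configuration ($\theta = \pi$, measure zero) is the direction resolved
by a fixed perpendicular tie-break. Exactly coincident repulsion
closest-points use a fixed tie-break direction.

## Systems and their desk-scale conditions

Three builders construct the simulated systems:

* **Two-filament system** — two antiparallel filaments along z,
  laterally 27 nm apart, barbed ends clamped to the walls they point at;
  motors centered between the filaments at uniform-random heights inside
  the overlap; cross-linkers at admissible site pairs in the overlap.
  Reference conditions: 19-um filaments in a 5×5×20 um domain, 2 motors
  (24 arms), 16 ACPs. Desk preset: 6-um filaments in a 5×5×8 um domain
  (4-um overlap), 2 motors, 6 ACPs — the reference linear ACP density
  (16 per 18 um of overlap) scaled to the shorter overlap and rounded
  up. Production time 10 s.
* **Bundle** — $N_F \times N_F$ lanes at 27-nm pitch, two filaments per
  lane at random height and polarity, periodic in all axes. Heights are
  rejection-sampled until the pooled filament arcs cover the periodic
  ring (with a 100-nm junction margin): random arcs leave an uncovered
  interval with appreciable probability (about 16% for eight 6-um arcs
  on a 14-um ring, and similarly at full scale), and a bundle severed by
  such a gap cannot bear ring tension at all — it is not a bundle in the
  measurable sense. The constraint conditions the generator on
  structural validity and leaves the distribution of valid bundles
  untouched. Desk preset
  for the thin-bundle efficiency experiment: $N_F = 2$ (8 filaments),
  6-um filaments on a 14-um ring, 4 motors (24 arms) anywhere ($f = 1$),
  120 ACPs — about one cross-link per 120 nm of bundle, so every
  inter-motor gap contains several. Production time 9 s.
* **Network** — a thin slab (periodic x,y; walls in z) of filaments
  grown by nucleation (rate $k_{n,A}$) and barbed-end polymerization
  (rate $k_{p,A}$) until a target actin mass, with in-plane random
  positions and orientations for filaments and motors. The rate ratio is
  calibrated from the uniform-age relation mean length $= k_p T/2$,
  mass $= k_n k_p T^2/2$, giving ~10-um mean filaments at the reference
  conditions. Note the resulting length distribution is broad but closer
  to uniform than exponential — constant-rate nucleation with
  constant-speed growth gives ~uniform filament ages.

Desk production times were chosen so the slow approach to the force
plateau (set by arm unbinding/rebinding cycles, ~0.2–5 s) is mostly
complete; the steady-window detector reports whether the 1% drift
criterion was met and otherwise averages the final half of the series.

## What the simulated conditions do and do not show

The generator emulates the geometry, mechanics and kinetics of
reconstituted actomyosin bundles/networks with permanent cross-linking:
discrete binding sites, bipolar motors with configurable architecture,
thermal fluctuations, buckling-mediated tension asymmetry. It does not
include actin turnover, cross-linker unbinding (slip or catch),
motor-filament self-assembly dynamics, hydrodynamic interactions, or
sarcomeric organization; conclusions drawn from passing tests therefore
apply to the permanently cross-linked, fixed-architecture regime. The
desk-scale systems shorten filaments and domains but keep every
per-element constant; observables that are ratios of forces (the
efficiency $\eta$) transfer across that scaling, while absolute forces
scale with the number of engaged arms.

Cluster-scale sweeps (98-filament bundles, motor counts in the hundreds
to thousands, the network motor-number scaling) are out of desk reach;
their qualitative content is covered by the overlap theory's monotone
laws, which the test suite verifies directly (E[$\Xi$] grows as motors
are added or confined, and the bare-zone-enlarged architecture
out-cooperates the spacing-enlarged one at equal length and arm budget).

## Known limitations

* The side-membership rule in $\Xi$ is one documented reading of the
  side restriction; alternatives shift $\Xi$ by at most the contribution
  of neighbors straddling a backbone end.
* At full stall in thin systems, filament and backbone segments stretch
  by 10–20% (the springs are as stiff as the integrator allows at the
  model's $\Delta t$); tension transmission is unaffected at steady
  state but geometry-sensitive quantities (overlap lengths measured from
  final configurations) inherit that distortion.
* Measured cross-section totals sum spring forces only; bending
  contributions across a plane are excluded by construction, consistent
  with the near-uniformity of plane totals at steady state.
* The walking step equals the 7-nm site spacing; velocities are
  faithful at the site-resolution level, not at the single-ATP level.
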