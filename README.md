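# pulsetrim

Topology optimization and reduction of one-dimensional arterial pulse-wave
networks.

`pulsetrim` is for cardiovascular modellers who run 1D blood-flow
simulations and have to decide *how many arteries the model actually
needs*. Every retained segment adds parameters (geometry, wall stiffness,
outflow impedance) with their own uncertainties; every removed segment
risks distorting the waveforms of interest. The package makes that
trade-off explicit: it finds the smallest network — within a well-defined
family of truncations — whose pressure/flow waveforms at user-chosen sites
stay within a stated error threshold of the detailed baseline model.

## What is inside

* **1D pulse-wave solver** — explicit MacCormack scheme for the
  pressure/flow form of the 1D equations with an elastic tube law
  (`P = P_dia + (β/A_d)(√A − √A_d)`, stiffness from the wall law
  `c_d² = (2/3ρ)[k₁ e^{k₂ r_d} + k₃]`), characteristic-based junction
  coupling with total-pressure continuity, stenosis loss junctions
  (`ΔP = K_v Q + K_e Q|Q|`), WK3 and coronary Windkessel outlets, run to
  periodic convergence. The network stepper is compiled (Rcpp); a
  seven-segment tree converges in well under a second.
* **Method 1, algebraic lumping** — steady Picard-linearized network
  solve; distal beds replaced by WK3 outlets with `R = (P̄ − P_out)/Q̄`,
  `R₁ = Z_c = ρc̄/Ā`, and compliance from the distal summation rules
  (terminal vessels via
  `C_t = (C_v R₂ + C_v R₁ + C R₂ + C_v R_v)/(R₂ + R₁ + R_v)`).
* **Method 2, per-site optimization** — the WK3 ODE is driven by the
  baseline flow at each cut face and `(R₁/R₂, C)` are optimized (total
  resistance fixed by Ohm's law) to minimize the average relative pressure
  error `ε_P,avg`.
* **Topology optimizer** — enumerates truncation candidates, walks them in
  ascending artery count, and returns the first (optionally certified
  minimal) candidate meeting the threshold.
* **Waveform metrics and clinical indices** — `ε_P,avg`, `ε_Q,avg`,
  systolic/diastolic/pulse-pressure errors, augmentation-pressure error
  with Savitzky–Golay-based inflection detection, iFR (last 30% of the
  cycle), FFR, and input-impedance spectra.
* **Scenarios** — normal ageing (stiffening ×2.5/×1.5, total resistance
  ×1.1, total compliance ÷2), aortic coarctation, heart-rate/ejection-time/
  stroke-volume rescaling of the inflow, coronary hyperaemia (α = 3 / 1.25).
* **Testkit** — deterministic single-vessel, binary-tree, ring and toy
  coronary fixtures, synthetic inflow/LV-pressure waveforms, and
  closed-form oracles (Poiseuille drop, Windkessel decay, WK3 impedance,
  dense nodal analysis).

## Worked example

Reduce a symmetric 7-segment arterial tree while keeping the average
relative root-pressure error under 2%:

```r
library(pulsetrim)

net <- make_fixture("binary_tree", generations = 3)   # 7 segments, 4 WK3 outlets
qs  <- quantity_spec(list(list(seg = "s1", pos = 0)),
                     metric = "eps_P_avg", threshold = 0.02)
out <- optimize_topology(net, qs, method = 2, exhaustive = TRUE)
out
#> <topo_outcome: 1 arteries, eps_P_avg = 0.004001 (threshold 0.02), method 2>
#>              candidate n_arteries        error feasible
#> 1                   s1          1 0.0040014093     TRUE
#> 2             s1+s2+s3          3 0.0011757471     TRUE
#> 3       s1+s2+s3+s4+s5          5 0.0005854604     TRUE
#> 4       s1+s2+s3+s6+s7          5 0.0005854604     TRUE
#> 5 s1+s2+s3+s4+s5+s6+s7          7 0.0000000000     TRUE
```

Reading the table: replacing the entire tree beyond the root by a single
fitted WK3 outlet ("1 artery") already keeps the cycle-averaged relative
root-pressure error at 0.40%, comfortably inside the 2% threshold, so the
optimizer returns the one-segment network; tightening the threshold to
0.2% forces it to keep the first bifurcation (3 arteries, 0.12% error).
The two 5-artery rows are the mirror-image truncations of one daughter
subtree — evaluated, feasible, but not minimal.

The same machinery compares the two reduction methods directly. On this
fixture, truncating after the first bifurcation and measuring at a distal
site gives `ε_P,avg` ≈ 0.58% for Method 1 versus ≈ 0.10% for Method 2 —
the algebraic method's matched-impedance outlets (`R₁ = Z_c`) overpredict
systole, and the optimizer's fitted `R₁ < Z_c` corrects exactly that.

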