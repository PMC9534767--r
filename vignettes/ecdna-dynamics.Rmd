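---
title: "Modelling ecDNA copy-number dynamics under random segregation and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ecDNA copy-number dynamics under random segregation and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdnadyn)
```

## The model

Extrachromosomal DNA (ecDNA) elements are circular, acentric DNA particles
that frequently carry amplified oncogenes in cancer. Because they lack
centromeres, mitosis does not split them evenly: after replication the $2n$
copies of a mother cell are partitioned between the two daughters
essentially at random. `ecdnadyn` implements this process at three levels
and keeps them mutually consistent:

1. **Single division** (`divide_ecdna()`, `divide_chromosomal()`,
   `fraction_distribution()`): daughter 1 receives
   $n_1 \sim \mathrm{Binomial}(2n, p)$ copies, $n_2 = 2n - n_1$, with
   $p = 1/2$ for unbiased random segregation. The inherited fraction
   $f_1 = n_1/(n_1+n_2)$ forms a wide, approximately Gaussian bell centred
   at $1/2$. The chromosomal comparator gives $f_1 = f_2 = 1/2$ exactly,
   except with a small mis-segregation probability $u$ (default $0.05$)
   under which $n_1 = n \pm 1$, each direction with probability $u/2$ — the
   symmetric reading that keeps $E[f_1] = 1/2$.

2. **Growing population** (`run_gillespie()`): a continuous-time pure birth
   process. Cells without ecDNA divide at rate $r^- = 1$ (time is measured
   in generations of ecDNA-free cells), cells with at least one copy at
   rate $r^+ = s$. A division doubles the mother's $k$ copies and splits
   them $\mathrm{Binomial}(2k, 1/2)$; an ecDNA-free cell can never found an
   ecDNA+ lineage. There is no death and no carrying capacity; runs stop at
   a target population size.

3. **Deterministic density** (`integrate_density()`): the expected class
   occupancies obey a master equation; normalized to a density $\rho_k$ of
   cells with $k$ copies, the neutral form is
   $$\partial_t \rho_k = -2\rho_k +
     2 \sum_{i \ge \lceil k/2 \rceil} \rho_i \binom{2i}{k} 2^{-2i},$$
   whose redistribution kernel $\binom{2i}{k}2^{-2i}$ is exactly the
   binomial division rule (the lower summation limit is
   $\lceil k/2 \rceil$; for odd $k$ the printed $i = k/2$ is not integral,
   and below it the binomial coefficient vanishes anyway).

These layers are linked by an exact correspondence: pooling all cells of
all replicates of the stochastic simulator estimates
$E[N_k(t)]/E[N(t)]$, which is precisely the density solved by the master
equation, because the expectation dynamics of the branching process are
linear. `run_gillespie_ensemble()` exploits this; the test suite asserts a
total-variation distance below $0.02$ between the two routes at $t = 3$.

### Selection and the ecDNA-free class

With selection, ecDNA+ classes ($k \ge 1$) follow
$$\partial_t \rho_k = s\,\partial_t \rho_k\big|_{s=1} + (s-1)\rho_0\rho_k,$$
while the ecDNA-free class requires care. Deriving from the unnormalized
equations — $\partial_t N_0 = N_0 + 2s\sum_{i\ge1} N_i 2^{-2i}$, then
normalizing by $N = N_0 + N_+$ with
$\partial_t N = N(\rho_0 + s(1-\rho_0))$ — gives
$$\partial_t \rho_0 = s\,\partial_t \rho_0\big|_{s=1}
  \;-\; (s-1)\rho_0(1-\rho_0).$$
The minus sign on the coupling term is forced by conservation of total
density ($\sum_k \partial_t \rho_k = 0$) and is the form implemented here;
with it, the closed-form moment solutions below follow exactly. (A plus
sign on this term, which one sometimes sees quoted, breaks both
conservation and the first-moment law; the numerical conservation check in
the test suite holds to $10^{-12}$.)

### Moments

Multiplying by $k^l$ and summing yields the moment dynamics. Key closed
forms, all exposed as functions and all verified numerically in the tests:

* Neutral first moment: $M^{(1)}(t) = M^{(1)}(0)$ — the mean copy number is
  a martingale. An exponentially growing population initiated by a single
  cell with one copy keeps mean $1$ forever, while the variance grows
  linearly ($\mathrm{d}M^{(2)}/\mathrm{d}t = M^{(1)}$).
* Under selection: $M^{(1)}(t) = e^{(s-1)\int_0^t \rho_0(\tau)\,d\tau}$
  (`selection_m1()`), and $M^{(2)}(t) = t\,M^{(1)}(t)$ (`selection_m2()`).
* Late-time scaling $M^{(l)}(t) \sim t^{l-1}$ (`moment_scaling_check()`).
* Fraction of ecDNA+ cells under neutrality: $f^+(t) = 2/(2+t)$
  (`neutral_fraction_positive()`) — neutral ecDNA survives only in an
  $\mathcal{O}(1/t)$ subpopulation. The full density integration decays
  with a log–log slope of $\approx -0.90$ on $t \in [10, 50]$, consistent
  with the $1/t$ law at these still-moderate times.

On the moment identity $M^{(2)}(t) = t$: taken literally it implies
$M^{(2)}(0) = 0$, which contradicts any non-empty initial condition (from
$\delta_{k=1}$, $M^{(2)}(0) = 1$). We read it as the asymptotic,
offset-free statement; the assertable differential form is
$\mathrm{d}M^{(2)}/\mathrm{d}t = M^{(1)}$, and that is what the tests
check ($M^{(2)}(t) - M^{(2)}(0) = t$ to within 1%). Similarly, the printed
second-moment relation under selection is used as stated
($M^{(2)} = t\,M^{(1)}$), without an extra factor $s$.

## Numerical choices

* **Simulator representation.** The state is a vector of counts per
  copy-number class (split into two neutral marker groups so a chromosomal
  scar can be tracked), not per-cell objects: the dynamics depend only on
  $k$. The compiled core (Rcpp) selects the dividing class by a two-level
  draw — ecDNA-free versus ecDNA+ by their aggregate rates, then a linear
  scan within — and advances time by exponential increments with total
  rate $N_0 + sN_+$. `select_dividing_cell()` additionally exposes the
  rejection-sampling formulation (propose a cell uniformly, accept with
  probability $\mathrm{rate}/\max(1, s)$), whose per-event cost is
  independent of the number of classes.
* **Seeds.** Every stochastic entry point takes a single integer seed;
  replicate $r$ of a replicated design uses `seed + r - 1`. The C++ core
  draws from R's RNG stream, so `set.seed()` governs everything.
* **Truncation.** The density lattice defaults to $k_{\max} = 512$ and is
  doubled automatically (up to 8192) whenever the density reaching the
  boundary exceeds $10^{-10}$; the worst-case $|1 - \sum_k \rho_k|$ is
  reported as `leaked_mass`. Neutral runs from $\delta_{k=1}$ barely use
  $k \approx 50$; selection runs need the headroom.
* **Integrator.** `deSolve`'s Adams method (the system is non-stiff) with
  `rtol = 1e-8`, `atol = 1e-12`. At these tolerances the first moment is
  conserved to well below $10^{-6}$, the bar used in the acceptance check.
* **Kernel.** $\binom{2i}{k}2^{-2i}$ is evaluated as `dbinom(k, 2i, 1/2)`,
  i.e. in log space, so no overflow at large $i$.
* **KS p-values.** Copy numbers are discrete; ties make the asymptotic KS
  p-value conservative. `ks_two_sample()` reports the standard asymptotic
  value (with an optional permutation p-value for tie-heavy data);
  `subsample_convergence()` uses Stephens' finite-sample correction
  $\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})D$, which we measured to
  be markedly better calibrated at $n = 25$ (empirical size 4.3% versus
  3.3% uncorrected, at nominal 5%).
* **Degenerate inputs.** Zero-copy founders are legal everywhere except
  the chromosomal model (chromosomal content is assumed positive);
  daughter pairs with zero total signal are accepted by the reader,
  flagged, and excluded from fraction analyses with a warning — whether
  such pairs were excluded in practice is not documented for the
  experimental assays, so exclusion-with-warning is the package's default.

## Scenario conventions

`run_crispr_c()` models the induction of a defined ecDNA by CRISPR
excision–religation: a fraction `q_ecdna` (default 0.15) of founder cells
receives exactly one ecDNA copy, and a fraction `q_scar` (default 0.15)
carries the neutral chromosomal scar left at the religated cut site. Scar
and ecDNA status are assigned **independently** — the observation that the
scar frequency stays flat while ecDNA initially declines under negative
selection argues against strong coupling, but co-occurrence in the same
founders is not excluded experimentally; independence is the package's
explicit convention. The scar passes to both daughters at every division,
so its frequency is a martingale under any schedule that does not price
scar status — the test suite verifies this to 3 s.e.m. across replicates.

Selection schedules are piecewise constant in `s` with one time unit per
generation of ecDNA-free cells; a "4 days + 14 days" drug protocol is
rendered literally as durations 4 and 14. Because the underlying process
is a pure birth process, indefinite growth is kept at bench scale by
passaging: when the culture reaches `passage_cap` (default $4 N_0$) it is
randomly downsampled, jointly over all classes and without replacement,
back to $N_0$. Subsampling is unbiased for every tracked frequency, so it
leaves the martingale structure intact while bounding runtime. The founder
population defaults to $N_0 = 10^4$ — a stand-in for a culture well; the
day-to-generation identification and $N_0$ are conventions, exposed as
configuration.

`run_drug_shift()` composes the same machinery into a
suppression–withdrawal experiment (`s_drug < 1` then `s_off > 1`),
reproducing the rapid, reversible copy-number shifts seen under targeted
therapy; only the direction and monotonicity of the response are asserted,
not absolute levels, which depend on the arbitrary phase durations.

## What the synthetic data emulate — and what they do not

The generators stand in for the study's three measurement types:

* `make_daughter_pairs()` — paired post-mitotic daughter counts
  (FISH in late mitosis), with founder copy numbers drawn uniformly from
  $\{20, \dots, 200\}$, read as a discrete uniform over integer copy
  numbers. Both daughters are recorded, as in paired experimental
  histograms; this makes the pooled fraction distribution exactly
  symmetric about $1/2$, which is a *construction* property, not evidence
  of unbiased segregation.
* `make_fish_table()` — interphase per-cell counts with optional binomial
  thinning (per-copy detection probability $\varepsilon$, default 1).
  Detection efficiency of the real assay is unquantified; thinning-only
  noise means no false-positive spots, no spot merging in crowded nuclei,
  and no segmentation error. Passing tests therefore show correctness of
  the pipeline, not robustness to imaging artefacts.
* `make_ddpcr_series()` — droplet digital PCR readouts: droplet occupancy
  is Poisson at a concentration proportional to the true junction
  frequency, the estimator is $-\log(\text{fraction negative})$, and
  frequencies are ratios to a reference (housekeeping) amplicon at
  `lambda_ref` copies per droplet (default 0.25). Saturation (all droplets
  positive) raises an error rather than returning an infinite estimate.

Defaults mirror the study conditions where stated (about 100 daughter
pairs per line; subsampling at sizes 25/50/100/500 with 500 resamples;
induction with ~15% ecDNA+ founders at exactly one copy; negative
selection $s = 0.5$ for 4 time units followed by 14 units of varying
positive selection). Where the source states larger compute scales
($10^7$ single divisions, populations to $10^{11}$ cells from clusters,
a $2\times10^6$-cell reference distribution), the package defaults are
desk-scale — $10^5$ divisions, $10^4$–$10^6$ cells, $10^6$-cell reference
— chosen because the quantities under test (distributions, moments,
rates) are invariant or convergent in these sizes; all scales remain
arguments.

## A worked neutral run

```{r neutral, eval = FALSE}
run <- run_gillespie(sim_config(n0 = 1, s = 1, n_target = 1e4, seed = 1))
summarize_population(run$final)[c("m1", "variance", "frac_pos", "shannon")]

sol <- integrate_density(init = 1, s = 1, t_max = 5, k_max = 512)
range(sol$moments$m1)          # conserved at 1
tail(sol$moments$variance, 1)  # ~ M2(0) + t - 1 = 5
```

## Known limitations

* One ecDNA species per cell; no cell death, spatial structure, or
  cell-cycle phase; no copy-number-dependent or balancing selection.
* The analytic kernel assumes unbiased segregation ($p = 1/2$); biased
  $p$ is available only in the single-division and (implicitly) not in
  the density machinery.
* The two-population closed form $f^+ = 2/(2+t)$ involves a loss-rate
  function with no explicit printed form; it is validated only
  qualitatively here (the $1/t$ scaling of the full density model).
* The rejection-rate clause of the subsampling analysis compares two
  test sizes that are both approximately the nominal level; its ordering
  is only marginally resolved at 500 resamples (see the calibration note
  above).
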