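---
title: "A degree-day phenology model of the European spruce bark beetle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A degree-day phenology model of the European spruce bark beetle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rity)
```

## The model

The European spruce bark beetle (*Ips typographus*) is the most
damaging insect pest of Norway spruce in Central Europe. Its seasonal
biology — when adults swarm in spring, when they colonise host trees,
how many filial generations and sister broods they complete before
winter — is governed almost entirely by temperature and photoperiod.
`rity` implements a daily stepping phenology model of that biology,
driven by nothing more than daily minimum, mean and maximum air
temperatures from a gridded nowcasting product (or a station), site
latitude, and a set of published constants.

The computation chain for every day $i$ at a location $x$:

1. **Forest air temperature.** Product temperatures $I$ are corrected
   to air temperatures $AT$ inside the forest stand with fixed linear
   models: $AT_{min} = 1.44 + 0.82\,I_{min}$,
   $AT_{mean} = 0.50 + 0.81\,I_{mean}$,
   $AT_{max} = 1.03 + 0.86\,I_{max}$.
2. **Bark temperature.** $BT_{min} = 0.56 + 0.99\,AT_{min}$,
   $BT_{mean} = -0.48 + 1.03\,AT_{mean}$,
   $BT_{max} = 0.03 + 0.99\,AT_{max}$.
3. **Effective bark temperature** $BT_{eff}$, the daily development
   increment in degree-days: zero at or below the lower development
   threshold $DT_L = 8.3\,°C$ and at or above the upper threshold
   $DT_U = 38.9\,°C$; linear, $BT - 8.3$, between $DT_L$ and the
   optimum $T_O = 30.4\,°C$; and the nonlinear form
   $(T_O - DT_L)\,(e^{\alpha BT} - e^{\alpha T_{max} - (T_{max}-BT)/\beta}
   - \gamma)$ between $T_O$ and $DT_U$, with
   $\alpha = 0.02876507$, $\beta = 3.5922336$, $\gamma = 1.24657367$,
   $T_{max} = 40.9958913$.
4. **Onset of swarming and infestation.** From the start date (7 March
   by default) a degree-day sum $\sum \max(0, I_{max} - 8.3)$ is
   accumulated on the *uncorrected* product maxima. Swarming is
   declared on the first day the sum has reached 53.0 dd while that
   day's $I_{max}$ exceeds the flight-activity threshold of 14.5 °C;
   infestation analogously at 155.6 dd.
5. **Brood development.** The first filial generation (F1) starts at
   infestation and accumulates $BT_{eff}$ (onset day included),
   expressed as a *relative thermal sum* $T_{sum} = \sum BT_{eff}/K$
   with $K = 557$ dd for complete development. Sister brood $S_j$ is
   initiated on the first day with $T_{sum,F1} > j - 0.5$, and filial
   generations F2 and F3 on the first day with $T_{sum,F1} > 1$ and
   $> 2$ respectively — each additionally requiring $I_{max} >
   14.5\,°C$ and day length $\ge 14.5$ h (the diapause gate). Every
   initiated brood accumulates its own relative thermal sum until
   31 October.
6. **Stages and generation counts.** A relative thermal sum maps to a
   stage (egg, larva, pupa, teneral adult, emerged adult; breakpoints
   0.1, 0.5, 0.6, 1.0), and broods whose final sum reaches 0.6 —
   pupal development complete — can overwinter and are counted as
   potential generations; filial and sister counts are reported
   separately.

The whole chain is run under three scenarios — MIN, AVG, MAX — that
drive development with the daily minimum, mean or maximum bark
temperature, bracketing the plausible development envelope at the
site. Onset detection (step 4) is scenario-independent by
construction, since it uses the raw daily maxima.

```{r}
w <- generate_series(climate_spec(seed = 7, year = 2020))
fit <- rity(w, latitude = 46.37)
summary(fit)
```

## Design choices where the design was open

Several points of the published formulation require a decision; the
package resolves them as follows and tests them as stated.

**Gates use the product maxima, not forest maxima.** The onset
conditions are written in terms of the uncorrected daily maximum
$I_{max}$, and the model deliberately distinguishes it from the forest
$AT_{max}$; only development (via bark temperature) uses the corrected
chain.

**Degree-day truncation.** The onset sum $\sum(I_{max} - 8.3)$ is
accumulated as $\sum \max(0, I_{max} - 8.3)$: a day colder than the
base contributes nothing rather than subtracting. This is standard
degree-day practice and prevents a cold snap from erasing an accrued
swarming cue.

**Onset is simultaneous, not retroactive.** An event is declared on
the first day on which the cumulative condition *and* that day's
flight gate hold together. A threshold crossed on a cold day does not
trigger the event retroactively once a warm day arrives; the warm day
itself is the onset.

**Inequalities exactly as printed.** Brood-initiation thresholds on
$T_{sum,F1}$ are strict ($> j - 0.5$, $> 1$, $> 2$), while the
degree-day onset sums and the day-length gate are non-strict ($\ge$).
No epsilon is added to any comparison; ties are resolved by plain
floating-point comparison. With a constant development rate of
0.1/day, F1 reaches exactly 1.0 on day 10 and F2 is initiated on
day 11.

**F3 is conditioned on $T_{sum,F1} > 2$, literally.** The natural
alternative ($T_{sum,F2} > 1$) gives slightly different F3 onsets
because F2's own onset can be gate-delayed; the printed form is
implemented.

**The optimum-temperature discontinuity is kept.** The linear branch
owns $BT = T_O$ and gives 22.1 dd there, while the nonlinear branch
just above gives ≈ 21.67 dd. The jump is implemented exactly as
printed, with no smoothing; the nonlinear branch is clamped at zero
from below (its value just under $DT_U$ is ≈ +0.014 dd, and parameter
edits could otherwise produce microscopic negatives).

**The diapause gate blocks initiation only.** Once a brood is
initiated it continues accumulating until 31 October even after day
length falls below 14.5 h; the gate appears only in onset conditions.

**Stage intervals are half-open.** The nominal stage ranges share
endpoints; the package assigns each interior breakpoint to the later
stage (0.1 is a larva, 0.5 a pupa, 0.6 a teneral adult, 1.0 an
emerged adult), a deterministic tie-break.

**Day length** is computed with the Cooper declination
$\delta = 23.44° \sin(2\pi(284+n)/365)$ and
$L = \tfrac{2}{15}\arccos(-\tan\phi \tan\delta)$ hours — the simplest
standard geometric formula, sun centre on the horizon, no atmospheric
refraction. The convention matters: at 46° N the date on which day
length drops below 14.5 h shifts by one to two days between the
geometric and refracted definitions, so `day_length()` exposes a
`horizon` offset for sensitivity checks. Leap years are handled by
calendar dates; the 365-day denominator error is far below 0.1 h.

**Separate generation counts.** Filial and sister broods are counted
separately; no half-weighting of sister broods into a single
voltinism index is applied, since the weighting is not part of the
model as published. The first sister brood's onset is reported as the
re-emergence date of the parental beetles.

**Sister broods are capped at three** (configurable via
`max_sister`), matching the filial cap; the $j$-th-brood rule is
otherwise unbounded.

## Calibration of the start date

The date from which the onset degree-day sum is accumulated is a
regional property. `calibrate_start_date()` finds it by iteration:
every candidate month-day in a grid (default 1 February – 30 April,
daily step) is used as the start date, onset of swarming and
infestation are re-predicted for every observed site-year, and the
candidate minimising the combined mean absolute error — the
unweighted mean of the swarming MAE and the infestation MAE — is
chosen, taking the *latest* candidate among ties. Site-years missing
one observation contribute only to the other term. A candidate whose
predictions cover fewer than 90 % of the observation pairs is
disqualified (threshold configurable), so a start date too late to
ever accumulate the thresholds cannot win by never predicting.
Because a later start can only remove accumulated degree-days,
predicted onsets are non-decreasing in the start date — a property
the test suite checks — and noise-free observations generated by the
model itself are always recovered with zero MAE.

## The synthetic weather generator

`generate_series()` emulates one year of a gridded product at a point:
the daily mean follows a seasonal sinusoid (defaults: annual mean
10 °C, amplitude 10 °C, peak at day 205 — a Slovenian lowland
climate), the minimum and maximum sit half the diurnal range (8 °C)
below/above it, and Gaussian noise (sd 1.5 °C) is added — outward
only (absolute-valued) for the min/max, so the ordering
$I_{min} \le I_{mean} \le I_{max}$ holds by construction rather than
by clipping, at the cost of the noise being unbiased only for the
mean. `generate_grid()` adds a deterministic south-to-north lapse and
a host-presence mask. Everything is seeded and leaves the caller's
RNG state untouched.

What the generator does *not* emulate: day-to-day autocorrelation,
weather fronts, elevation, or any spatial noise structure beyond the
lapse gradient. Tests passing on this synthetic weather therefore
demonstrate the correctness of the *computation* — thresholds, gates,
accumulation, ordering — not the model's predictive skill on real
forests, which depends on real forcing data.

## Numerical choices and problem sizes

All thresholds are compared in plain double precision. The
brute-force cross-check re-derives every cumulative sum from scratch
each day with naive loops and must agree with the vectorised engine
on 50 seeded synthetic years; ordering and dominance properties are
checked on 200 seeded years; calibration recovery uses 5 sites × 3
years over the full February–April candidate grid; grid/point
consistency uses a 10 × 10 cell synthetic cube with 20 % of cells
masked. These sizes exercise every code path while keeping the whole
suite under a minute of compute.

Grid data are serialised as plain text: a `key=value` metadata file,
a long-form CSV of the three daily temperature fields, and ESRI ASCII
(`.asc`) rasters for the host mask and all map outputs (onset
day-of-year as integers with a −1 NoData sentinel declared in the
header). Cell latitudes are taken from the geotransform at cell
centres; for a projected CRS a per-run latitude override is required.

## Limitations

The model predicts *potential* phenology: no mortality, predation,
dispersal, host depletion or population dynamics. Winter development
and multi-year carryover of partially developed broods are out of
scope — each year starts fresh on 7 March. The temperature-correction
coefficients are taken as given and are specific to the conditions
under which they were fitted; applying the model far outside Central
European montane spruce forests would require refitting them, which
this package deliberately does not do.
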