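---
title: "Quantifying fear synchrony in mouse dyads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fear synchrony in mouse dyads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearsync)
```

## The problem

When two fear-conditioned mice are exposed to a conditioned stimulus (CS)
together, their freezing bouts tend to coincide more often than chance.
`fearsync` quantifies that coordination from the only data the paradigm
produces: frame-indexed annotations of freezing bouts (start and end frame
per bout, one subject per row), recorded at 4 frames/s over a 60-s pre-CS
baseline and a 120-s CS period. All analyses run on the CS segment — 480
frames at the defaults — unless a window is supplied explicitly.

Two conventions matter and are fixed package-wide. Frames are 0-based and
bouts are half-open intervals `[start, end)`; annotator tables, which record
the first and last frozen frame inclusively, are converted on ingest
(`end = last + 1`, controlled by `end_convention`). A freezing bout must
last at least 1 s (4 frames); overlapping or abutting bouts are rejected
rather than merged, because under the bout definition adjacent bouts are one
bout and their presence indicates an annotation error. Sub-second *gaps*
are legal: the definition constrains bout length, not gap length.

## The synchrony statistic

For a dyad with CS freezing traces $a_t, b_t \in \{0,1\}$ over $n$ frames,
with freezing fractions $p_a$ and $p_b$:

* observed overlap $O = \tfrac1n \sum_t a_t b_t$;
* chance overlap $E = p_a\, p_b$ (independence);
* raw synchrony $S_{\text{raw}} = (O - E)/\sigma_0$, where $\sigma_0$ is the
  null spread of the overlap;
* corrected synchrony $S = S_{\text{raw}} - \bar S_{\text{virtual}}$, the
  group's mean virtual-dyad synchrony being the *non-social component*.

**Null spread.** Freezing traces are strongly autocorrelated (bouts last
seconds), so frames are not exchangeable and a Bernoulli null would
understate $\sigma_0$ and inflate $|S|$. The default null therefore rotates
one trace circularly against the other: rotation preserves each animal's
bout-length and autocorrelation structure exactly while destroying
alignment. `null_overlap_spread()` enumerates every nonzero rotation when
`n_surrogates` at least equals their number (making short-trace results
exactly reproducible and testable against brute-force enumeration) and
samples rotations with a seed otherwise; the default is 1000 surrogates. A
closed-form binomial mode, $\sigma_0 = \sqrt{E(1-E)/n}$, is retained for
speed and for closed-form unit tests.

**Degenerate dyads.** If a subject freezes in no frame or every frame, the
standardized score is undefined (the null has zero spread). Such dyads are
excluded with a warning rather than assigned 0 — an arbitrary 0 would pull
group means toward zero and silently dilute real effects.

**Virtual dyads.** The non-social component — synchrony produced merely by
both animals following the same CS-locked freezing time course — is
estimated from *virtual dyads*: all pairings of the group's subjects that
were never tested together. A same-sex group of $k$ real dyads ($2k$
subjects) yields $\binom{2k}{2} - k$ virtual dyads (760 for $k=20$, 1012
for $k=23$); opposite-sex groups use male×female cross pairs only
($k^2 - k$), because a virtual dyad must be a conceivable experimental dyad
of its group. Subtracting the virtual mean centers the virtual population
at zero by construction; the subtraction is applied per experimental group.

## The four-state decomposition

Per frame, a dyad occupies one of four states: 0 (both freeze), 1 (A
freezes, B moves), 2 (A moves, B freezes), 3 (both move); 0 and 3 are
*congruent*, 1 and 2 *incongruent*. The 4×4 transition matrix (16 cells,
4 self-loops) always sums to frames − 1.

Motif counting runs on the run-length-collapsed sequence, because the
motifs concern state *changes*: dwell frames inside a state must not break
a motif. Two motif families are counted:

* **follow** — a transition between the two congruent states, directly or
  via one incongruent state (one animal switches, the partner copies it);
  events ending in state 0 are follow-to-freeze, in state 3 follow-to-move.
  On any collapsed sequence without same-frame double switches, congruent
  visits alternate only at follow events, so the two subcounts differ by at
  most 1 (verified by brute force in the test suite); their sum is the
  follow count.
* **retroact** — a two-step loop leaving and re-entering the same congruent
  state via one incongruent state (the animal that broke the state reverses
  itself): 0→{1,2}→0 is retroact-to-freeze, 3→{1,2}→3 retroact-to-move.

Three edge rules were genuinely open and are resolved as follows. Direct
0↔3 adjacencies (both animals switching within one frame) count as follow
events — they are followings too fast for 4-fps sampling to resolve — and
are reported per dyad (`n_direct`) since many of them indicate coarse
sampling. Excursions through *both* incongruent states (e.g. 0,1,2,3) count
as neither motif in the default strict mode, which reads "via one
incongruent state" literally; a lenient mode accepting any incongruent
excursion is available for sensitivity analysis. Direct 1↔2 adjacencies
terminate motifs in strict mode.

## Group statistics

* **Freezing equalization**: per dyad, $|p_a - p_b|$ (in percent) when
  tested together (PAIR) versus in separate chambers (SINGLE); compared with
  the Wilcoxon matched-pairs test.
* **Balanced partner correlation**: correlating "animal 1" vs "animal 2"
  freezing is spurious if one column systematically holds the higher
  freezer. Dyads are sorted by mean freezing (descending) and the high
  freezer is assigned to alternating columns, so both columns hold equal
  numbers (±1) of high and low freezers. Within-dyad ties are resolved by
  subject-id order and logged. Opposite-sex dyads use the fixed
  male-column-1 assignment instead. Pearson by default, Spearman by flag.
* **Top/bottom split**: the `floor(0.4 N)` dyads with highest and lowest
  corrected synchrony; `floor` guarantees disjoint subsets for every $N$;
  boundary ties break by dyad id with a warning.
* Hypothesis tests are delegated to the standard library routines
  (`t.test`, `wilcox.test`, `cor.test`) and reported descriptively.

## The synthetic cohort generator

No recordings ship with the package, so every stage is validated against a
generator that produces dyads with the statistical structure the analysis
assumes. Each animal is a two-state (moving/freezing) chain stepped per
frame with time-varying hazards:

| parameter | default | meaning |
|---|---|---|
| `on_pre`, `off_pre` | 0.010, 0.25 /frame | pre-CS: rare, short freezing |
| `on_peak` | 0.45 /frame | freeze-onset hazard at CS onset |
| `on_asym`, `on_decay_s` | 0.030 /frame, 25 s | hazard relaxes exponentially |
| `off_cs` | 0.090 /frame | CS freeze-offset hazard |
| `min_bout_frames` | 4 | 1-s minimum bout at 4 fps |
| `tau_s` | 2 s | retroact memory window |
| `subject_sd` | 0.25 | log-normal spread of individual onset multipliers |

The CS onset hazard spike followed by exponential relaxation produces the
canonical freezing-probability time course: a rapid rise that reaches peak
level within ~5 s of CS onset, then a slow decline. Because the curve
plateaus after the rise, the package's tests assert "peak within 5 s" as
the first-5-s maximum reaching ≥95% of the session-wide maximum — the
literal argmax frame on a plateau is sampling noise. The defaults were
chosen once so that cohort mean CS freezing falls in the 30–70% band
typical of cued-fear tests (≈54% here); they are documented, not fitted.

Minimum bout length is enforced by refractory suppression — after entering
freezing an animal cannot switch for `min_bout_frames − 1` frames, and
onsets too close to the session end to complete a bout are suppressed —
rather than post-hoc merging, which would distort the coupling dynamics
under test. Every simulated ethogram passes the same validation as ingested
annotation tables.

**Coupling.** Social coupling acts only while the dyad is incongruent and
is hazard-multiplicative, so $\gamma = 0$ is exactly neutral:

* $\gamma_{\text{follow}}$ multiplies (by $1+\gamma$) the hazard of the
  animal that did *not* break the last congruent state to copy its
  partner's new state. The breaker is excluded deliberately: boosting every
  "match the partner" hazard would also accelerate the breaker's own
  reversal and conflate the follow mechanism with the retroact one.
* $\gamma_{\text{retroact-freeze}}$ / $\gamma_{\text{retroact-move}}$
  multiply the *breaker's* reversal hazard for `tau_s` seconds after it
  broke joint freezing / joint moving.

Reversal and partner-follow are competing risks for the same incongruent
episode, so a plain reversal boost necessarily starves the partner of
follow opportunities and drags follow counts down as retroact coupling
rises. The retroact coupling is therefore *flux-preserving*: it also
multiplies the break hazard out of the corresponding congruent state by the
factor by which boosted reversal shortens episodes,
$(h_p + h_b(1+\gamma))/(h_p + h_b)$, keeping the expected number of
partner-follow events constant to first order. A retroacting animal is one
that makes more self-corrected exploratory breaks. With this design the
two mechanisms dissociate cleanly in simulation: the follow grid moves
synchrony and follow counts monotonically while retroact counts do not
rise; the retroact grid multiplies retroact-to-freeze counts while follow
counts stay within ~25% of baseline (residual second-order drift from
refractory and dwell-time effects). One consequence, worth knowing when
interpreting simulated cohorts: flux-preserving retroact coupling is
roughly synchrony-neutral, so unlike the follow mechanism it does not by
itself create a count-synchrony correlation.

**Buffering/equalization.** Each subject's freeze-onset hazard carries a
log-normal multiplier (its individual fear level). `buffering_shift`
$\in [0,1]$ shrinks the two partners' log-multipliers toward their mean in
the PAIR configuration, emulating fear buffering; `configuration =
"SINGLE"` re-simulates the same subjects (same multipliers) with coupling
and buffering off, so PAIR-vs-SINGLE equalization contrasts use matched
animals, as in the counterbalanced two-test design the data model assumes.

**Playback partners.** `playback_partner()` replays a fixed ethogram as one
dyad member (receiving no social input) against a live simulated subject —
the robot-ball-style control. With $\gamma = 0$ the subject ignores the
playback (non-social object); with $\gamma > 0$ it couples to it (socially
salient object).

**Seeds.** A single pipeline seed is fanned out deterministically per dyad
id and operation (`derive_seed()`, a Lehmer-style mix of seed and key), so
results are bit-identical regardless of the order dyads are simulated or
analysed in.

## What the generator does and does not emulate

It reproduces: the CS-locked rise-then-decline freezing dynamics, the 1-s
minimum bout with legal sub-second gaps, individual differences in freezing
level, follow- and retroact-type coupling with tunable strength and
across-dyad heterogeneity, fear buffering, uncoupled (SINGLE-like) controls
and playback partners. It does not emulate: annotator noise and frame
jitter, within-session habituation beyond the hazard relaxation, sex- or
treatment-specific physiology (groups differ only by the parameters you
give them), or bout-duration distributions beyond geometric-with-refractory.
Passing tests therefore show that the *pipeline* recovers the structure it
is designed to detect — not that real mice obey this generative model.

## Problem sizes and numerical choices

The test suite and the acceptance script run at study-scale sizes chosen as
a deliberate compromise between statistical resolution and desk-scale
runtime: cohorts of 20–23 dyads (the same-sex group sizes the data model is
built around), 10 such cohorts (200 dyads) for null calibration, 5-point
coupling grids with 60–100 dyads per point, and 1000 circular-shift
surrogates per dyad (200 in the grid sweeps). Motif counters are verified
against an independent brute-force scanner on 10,000 random sequences, and
the surrogate null against exhaustive rotation enumeration on traces up to
64 frames, where enumeration is exact.

Remaining numerical conventions: hazards are capped at 0.9/frame; the
virtual-dyad mean is taken over non-degenerate virtual dyads; correlation
functions refuse groups with fewer than 3 complete observations; and the
analysis reruns byte-identically for a fixed seed (checked in the test
suite via on-disk checksums).

## Known limitations

* The standardization denominator is a modelling choice; circular-shift and
  binomial nulls give different absolute scales, so corrected synchrony
  values are comparable only within one null method.
* Group-level correction assumes the virtual dyads of a group share the
  real dyads' non-social dynamics; treatments that alter freezing dynamics
  *and* group composition would confound it.
* At 4 fps, same-frame double switches are unresolvable; they are counted
  as direct follows and flagged, but a higher frame rate would disambiguate
  them.
* The simulator's dissociation properties are first-order; very strong
  retroact coupling (γ ≫ 4) accumulates second-order drift in follow
  counts.
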