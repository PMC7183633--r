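---
title: "How emaflow schedules, randomises and simulates mHealth studies"
author: "emaflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How emaflow schedules, randomises and simulates mHealth studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emaflow)
```

## The problem

Smartphone-based studies — ecological momentary assessment (EMA),
randomised controlled trials, just-in-time adaptive interventions (JITAI)
and micro-randomised trials (MRT) — are defined operationally by a set of
interacting rules: when prompts fire and for how long they remain
answerable, how participants are allocated to arms, how survey content is
shuffled or conditionally revealed, and what happens to responses recorded
while offline. Errors in any of these rules are expensive to discover once
a study is in the field. `emaflow` implements the rules as a deterministic,
clock-injected engine over a JSON protocol format, so that a complete study
design can be validated and exercised with synthetic participants before
deployment.

This vignette documents the semantics the engine implements, the choices
made where a written rule underdetermines behaviour, what the simulator
does and does not emulate, and the problem sizes the test suite uses.

## Protocol model

A protocol is one JSON document: study metadata, a non-empty list of
condition labels, and ordered modules, each with a schedule, optional
feedback graph, and sections of elements. The parser applies defaults
(`required = false`, `shuffle = false`, `condition = "*"`,
`cache_media = false`), reports schema violations with a JSON-path to the
offending node, and in strict mode rejects unknown keys (the default mode
warns, which tolerates forward-compatible extensions). Element `text` may
contain a small HTML subset (`b`, `i`, `u`, `br`, `p`); the engine stores
it verbatim and never interprets it — markup only matters to a rendering
client, and stripping happens solely in exports that claim plain text.

Validation is diagnostic-based rather than exception-based so that
authoring tools can show all problems at once. Beyond structural
invariants (unique ids, non-empty sections, slider `min < max`), the
referential rules are: graph variables must name a numeric element of the
same module (slider, number, or yes/no); branching sources must be
sliders, yes/no, checkbox or radio elements *earlier in document order*
(which makes dependency cycles unrepresentable); randomisation groups must
lie within one section, because rendering is per page; and a
single-member group is flagged as a warning, not an error — it is
semantically a no-op rather than a defect.

## Scheduling semantics

All datetimes in the engine are timezone-naive local times (ISO-8601 on
output, no zone designator). A "day" is a calendar day delimited by local
midnight, and `start_offset_days` counts calendar days from the enrollment
date, not 24-hour blocks — a participant enrolling at 23:50 still gets the
day-0 prompts dated that calendar day. This matches how study staff reason
about schedules and avoids DST arithmetic entirely, at the cost of
ignoring timezone travel mid-study (a documented non-goal).

Schedule expansion produces one *occurrence* per (day, clock time) pair
over `duration_days` days, truncated with a warning at the expansion
horizon. The scheduling types compose as follows:

* **Fixed (sticky)**: one occurrence, permanently open and repeatable;
  with a negative start offset it is available from the day prior to
  enrollment (offsets below −1 floor at −1). Duration and timeout are
  ignored, and validation warns if they are set.
* **Interval**: occurrences become open at their alert time and remain
  open indefinitely until responded — responding removes them from the
  task list.
* **Random**: each occurrence's alert time is jittered independently by an
  integer number of minutes drawn uniformly on [−m, +m] around the nominal
  time. "Within m minutes relative to the notification time" admits
  one-sided and two-sided readings; the symmetric law was chosen because
  "relative to" suggests both directions and a symmetric law is the
  easiest to verify empirically (the tests Kolmogorov–Smirnov-check 10,000
  replicate draws against the uniform envelope). Jitter is frozen at
  expansion time: re-expanding with the same seed reproduces the same
  alerts. Whether a fielded platform would redraw jitter on re-expansion
  is unspecified behaviour; freezing is the only choice compatible with
  end-to-end reproducibility.
* **Timeout**: the occurrence expires exactly `timeout_minutes` after its
  alert if unanswered. Enforcement is double-ended: an expired occurrence
  cannot be opened, and an instance opened in time cannot be submitted
  after its close time. The second half is the conservative reading of
  "becomes unavailable" — without it a participant could hold a prompt
  open past its window, which would undermine EMA's in-the-moment
  rationale.
* **Mixed**: random and timeout combine freely; the timeout window is
  anchored at the jittered alert time.

Because mobile operating systems cap the number of local notifications an
app may schedule, the engine maintains only the next `NOTIFICATION_CAP`
(default 30, overridable for testing) pending alerts: at every home-screen
refresh the earliest future alerts across all modules are recomputed.
Simultaneous alerts tie-break by (alert time, module document order,
occurrence index) — document order is the only stable, author-visible
ordering available, and a deterministic tie-break is required for
reproducibility (the tests pin it with a 31-way tie).

## Randomisation

Four independent mechanisms, all drawing from named, seeded streams:

* **Condition allocation**: one uniform draw over the protocol's condition
  labels at enrollment, immutable thereafter. Modules are then filtered to
  those assigned the participant's arm or the wildcard `"*"`. (The
  alternative design in which researchers host one protocol file per arm
  needs no engine support — it is just two files.)
* **Section shuffle** and **question shuffle**: fresh uniform permutations
  at every module access, at module and section level respectively.
* **Randomisation groups**: at every access, exactly one element of each
  group is shown, chosen uniformly; the rest are hidden for that access.
  Repeated accesses of a sticky module therefore realise a
  within-subject / micro-randomised exposure sequence.

Streams are derived per participant and per purpose (allocation, jitter,
render, behaviour, id) from a hash of `(study id, participant key,
purpose, master seed)`. This has two consequences worth stating: adding
modules to a protocol never perturbs condition allocation, and enlarging a
simulated cohort never changes the trajectory of an existing participant
index. Streams carry private copies of R's RNG state, so engine calls
never disturb the caller's `.Random.seed`.

## Branching

An element with a branching rule names an earlier source element, a
trigger value, and a polarity: `hide_if_matched = true` hides the element
when the source's response matches, `false` shows it on match and hides it
otherwise (both directions are needed to express "become visible or
hidden"). Matching is equality for yes/no and radio, membership for
checkbox, and for sliders either a bare number (equality) or a strict
comparator string `">n"` / `"<n"` — `≥`/`≤` are deliberately omitted
because integer thresholds express them. Two conservative policies
complete the semantics: a dependent of an *unanswered* source is hidden
(conditional content appears only once triggered), and a hidden source
hides all its dependents, cascading down chains. Since sources precede
dependents in document order, a single forward pass reaches the fixpoint;
the test suite checks this pass against an independent recursive oracle,
exhaustively over the response domain for small modules and on large
seeded samples up to 12 branch-relevant elements (yes/no domains
enumerated fully; sliders sampled at their bounds and at threshold ± 1 for
every rule referencing them).

Answers a participant typed into an element that subsequently became
hidden are retained in memory — re-revealing the element restores them —
but are excluded from the submitted record. Whether a fielded app clears
or retains such answers is unobservable from the outside; exclusion from
the record is the safety-relevant half, and retention in memory is the
friendlier UI assumption.

## Session runtime and offline delivery

Enrollment draws an anonymous 8-decimal-digit identifier (leading zeros
allowed; collisions within a run are redrawn, enforcing local uniqueness),
allocates the condition, and expands all in-condition schedules over the
horizon. Submission requires every *visible* required element to be
answered — a required element hidden by branching or by a group draw
imposes no requirement. Records carry participant id, module id/name,
occurrence index, the answered visible responses (instructions and media
contribute no value), response and alert timestamps, platform, and
condition — the payload a deployment would POST to the researcher's
endpoint, abstracted here as a pluggable sink.

Completed records join an in-order offline queue. Flushing moves records
to the sink in FIFO order; a sink failure mid-flush leaves delivered
records uploaded and the rest queued, giving at-least-once delivery with
no loss and no duplication across retries, and the invariant
`#completed = #queued + #uploaded` holds at every instant before
withdrawal. Withdrawal deletes the queue without delivery, preserves
already-uploaded records, closes all open and future occurrences, and is
idempotent; any later session operation is a terminal-state error. Upload
retry cadence is not specified anywhere authoritative; the simulator
flushes at the next online contact and closes every trajectory with a
final online flush, which exercises the queue contract without modelling
network weather.

## The simulator: what it does and does not emulate

`simulate_cohort()` drives each synthetic participant through the real
runtime — the same scheduling, randomisation, branching and queueing code
paths a deployment would execute — under a behaviour model with four
levers: `compliance_prob` (probability an alerted occurrence is completed
before it closes), a response-latency distribution (uniform or
exponential minutes after the alert, truncated below the timeout for
timeout modules so a compliant response is by construction in-window),
per-element response samplers (uniform or clipped-Gaussian sliders,
uniform choices, fixed text token), and `offline_prob` (per-submission
probability the network is down). Defaults are full compliance, uniform
1–15-minute latency, uniform responses, always online — the transparent
baseline against which the conservation properties are exact. Simulated
time is event-driven: the clock jumps from alert to alert, so wall time
scales with the number of occurrences, not the study length.

The simulator is a verification instrument, not a psychological model. It
does not emulate: latent-trait heterogeneity between participants (one
behaviour model per cohort, with scripted overrides for deterministic
scenarios), time-of-day or fatigue effects on compliance, measurement
reactivity, attrition as a process (withdrawal is available but not
stochastic), or notification-delivery failures. Consequently, passing
tests demonstrate that the *engine* honours its contracts under the stated
behaviour distributions — they say nothing about how human participants
will respond.

## Numerical and degenerate-input choices

* Jitter of zero width is defined to be byte-identical to no jitter, and
  consumes no RNG draws.
* Elapsed-time annotations floor to whole minutes ("21 minutes ago").
* Latencies in exports are fractional minutes, clamped at zero.
* Yes/no responses are coded no = 0, yes = 1 for graphing; only slider,
  number and yes/no elements are valid graph variables, enforced at
  validation.
* Checkbox responses explode to one long-table row per selected option,
  with a `value_set_size` column so the original set is reconstructible.
* An empty record set exports a header-only CSV and an empty JSON-Lines
  file.
* Feedback-graph series keep the most recent `max_points` completions in
  chronological order; ties in response time are impossible within one
  participant-module because submissions are strictly ordered events.

## Problem sizes used by the test and acceptance suites

Distributional checks run at the sizes where 3-standard-error bands are
meaningfully tight while keeping the whole suite in a few minutes on one
CPU: 10,000 draws for condition allocation, group choice (chi-square) and
jitter uniformity (Kolmogorov–Smirnov); 6,000 accesses for 3-element
shuffle coverage; 10,000 enrollments for identifier-format checks;
compliance recovery on EMA cohorts of 200 participants × 42 prompts
(8,400 Bernoulli trials per programmed rate); branching-oracle
equivalence on more than ten thousand module-response combinations; and
byte-level determinism on 50-participant micro-randomised runs.

## Known limitations

The engine deliberately stops at the platform boundary: no UI rendering,
no push-notification transport, no media download or caching (media are
opaque URLs), no HTTP POST (sinks are in-memory or files), no
localisation, and no timezone/DST arithmetic. Cross-module branching and
compound branching conditions are out of scope — rules are single
source–value pairs, as is standard in this class of platform. Stratified,
blocked or adaptive randomisation is not provided; allocation is simple
randomisation, which is what double-blind in-app enrollment supports.
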