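# ruminate

Non-contact monitoring of cattle rumination from facial-keypoint
trajectories.

Rumination (chew count, rumination duration, chewing frequency) is a core
welfare and health indicator for cattle, classically monitored by hand or by
wearable sensors. A video alternative runs a pose model on barn footage and
tracks two facial keypoints — nose and mouth. **ruminate** implements
everything downstream of the pose model: it takes the per-frame keypoint
trajectory and turns it into validated rumination indicators.

## Method

For each frame *i* the motion curve is the Euclidean nose–mouth distance

d_i = sqrt((x₁ᵢ − x₂ᵢ)² + (y₁ᵢ − y₂ᵢ)²),

which oscillates quasi-sinusoidally, one cycle per chew, with per-cycle
amplitude and period variation. After zero-phase low-pass smoothing
(Butterworth, 3 Hz cutoff at 30 fps by default; a median filter is available
for comparison), chews are counted by multi-condition threshold peak
detection: index *i* is an accepted chew iff

* d_i − d_{i−1} > 0 and d_i − d_{i+1} > 0 (strict local maximum),
* d_i > threshold, where the threshold is the **median** of the distance
  series (rest-period wobble stays below the median; chew crests exceed it),
* peak_index[i] − peak_index[i−1] > 20 frames (at 30 fps; rescaled for other
  rates), suppressing double counts from head shaking.

Accepted peaks are grouped into bouts; inter-chew gaps above 3 s are treated
as rests and excluded from the rumination duration, and chewing frequency is
the chew count divided by that duration. The package also implements the
keypoint-evaluation metrics (OKS, AP, mAP@0.5:0.95, precision, recall) and
per-video chew-count error statistics, plus a seeded synthetic trajectory
generator with exact ground truth for validation.

## Worked example

```r
library(ruminate)

# a 60-chew session with a 5 s rest bout and 1 px keypoint jitter
sim <- generate_chew_trajectory(
  chew_signal_config(n_chews = 60, rest_bouts = list(c(30, 5)), seed = 14))
summarize_session(sim$trajectory)
#> <session_summary>
#>   chews:               60
#>   rumination duration: 48.20 s (5.80 s rest excluded)
#>   chewing frequency:   1.245 chews/s
#>   bouts:               2
```

All 60 simulated chews are recovered; the inserted 5 s rest is excluded from
the duration (the excluded gap is measured crest-to-crest, so it exceeds 5 s
by the two flanking half-cycles), and the frequency ≈ 1.25 chews/s falls in
the normal bovine rumination range.

Validating counts against manual observation:

```r
counts <- read_manual_counts(system.file("extdata", "manual_chew_counts.csv",
                                         package = "ruminate"))
evaluate_counts(counts)
#>  video_id duration_s assessed measured relative_error_pct
#>         1         74       83       79               4.82
#>         ...
#> Mean relative error: 5.60 %
#> Standard error (population): 2.23 %
#> Accuracy: 94.4 %
```

The same pipeline is scriptable from a shell via `exec/ruminate`
(subcommands `analyze`, `simulate`, `eval-counts`, `eval-keypoints`); flags
override a YAML config (`--config`), which overrides the defaults, and every
run logs its fully resolved configuration to stderr.

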