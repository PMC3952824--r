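# resectrack

Single-cell quantification of DNA double-strand-break (DSB) resection from
live-cell fluorescence movies.

When an endonuclease cuts a chromosome, the cell resects the DNA ends
5′→3′ to produce the single-stranded tails that commit it to repair by
homologous recombination. In budding yeast this can be watched in single
cells by placing two ParB/*parS* fluorescent cassettes next to the cut
site: ParB oligomerizes on double-stranded *parS* DNA into a visible
focus, and because ParB binds only dsDNA, the arrival of the resection
front at a cassette's distal end extinguishes its focus. Two cassettes —
INT1 (mCherry, distal end 1231 nt from the cut) and INT2 (GFP, distal end
7612 nt) — turn focus-loss times into a two-point time-stamp of the
resection front.

`resectrack` re-implements this assay end to end as a tested pipeline:

* **Synthetic microscopy** — dual-channel burst time-lapse movies of one
  nucleus per cell with full ground truth: cleavage times drawn from a
  Gaussian truncated at 10 min post-induction, a commitment lag before
  resection onset, slow-then-fast resection extinguishing INT1 then INT2,
  free ↔ confined mobility switching after cleavage, an exponentially
  bleaching background, Poisson shot noise and Gaussian read noise.
* **Detection and tracking** — matched-filter spot detection (radius 4 px,
  top 0.1 % intensity retention, no score cutoff) with sub-pixel centroid
  refinement, greedy nearest-neighbour linking within a 10 px radius, and
  strict scoring of tracks longer than 15 consecutive frames.
* **Quantification** — background-normalized focus-intensity traces
  (100 % at t0) and focus-loss calling by intensity threshold and by
  persistent detection absence.
* **Chromatin dynamics** — time-averaged mean-square displacement (MSD)
  per track, ensemble averaging, and the diffusion coefficient from the
  slope of the MSD over the first 2 s (`D = slope/4` for 2D tracking, fit
  with an intercept that absorbs localization noise), optionally
  normalized to the uncut-locus reference `D = 1.9×10⁻² µm²/s = 100 %`.
* **Resection kinetics** — loss-time distributions (Gaussian moments),
  resection durations anchored at the earliest cleavage time (10 min),
  slow-phase speed `v = 1231 nt / duration`, fast-phase speed
  `v = (7612 − 1231) nt / (t_loss,INT2 − t_loss,INT1)`, and the
  repair-commitment delay as the difference of mean INT1 loss times
  between genotypes.

The headline arithmetic the pipeline reproduces: a wild-type INT1 loss at
25 min gives a 15-min duration and 1231/15 ≈ 82 nt/min; a Ku-less
(*yku70*) loss at 12 min gives 2 min; a 4-min INT1→INT2 interval gives
(7612−1231)/4 ≈ 1595 nt/min of extensive resection (>1200 nt/min); and
the wild-type-minus-mutant mean loss difference estimates the ~10-min
commitment to homology-directed repair. After cleavage the damaged locus
transiently drops from free diffusion to a confined state
(`D ≈ 0.003 µm²/s`, under 30 % of the uncut reference) before recovering.

## Worked example

Simulate and analyse a wild-type and a *yku70* cohort (12 cells each) and
print the kinetics report:

```r
library(resectrack)
res <- runPipeline(presets = c("wt", "yku70"), nCells = 12, seed = 42,
                   acqOverrides = list(totalDurationMin = 60))
res$report
```

```
ResectionReport over 2 scenario(s)
  wt:
    INT1: lost 67%, t_loss 31.1 +/- 3.7 min [28.0, 38.0] (n=8)
    INT2: lost 0%
    slow-phase speed: 68.4 nt/min (earliest-based), 58.3 (mean-based)
  yku70:
    INT1: lost 50%, t_loss 16.7 +/- 1.0 min [16.0, 18.0] (n=6)
    INT2: lost 50%, t_loss 20.3 +/- 1.5 min [18.0, 22.0] (n=6)
    slow-phase speed: 205.2 nt/min (earliest-based), 184.6 (mean-based)
    fast-phase speed: 1861 nt/min (n=6, interval 3.7 min)
  commitment delay (INT1): 14.5 min
```

Reading it: two thirds of wild-type cells were cut and lost INT1 around
28–38 min while INT2 always persisted (resection halts before 3.4 kb);
*yku70* cells lost INT1 at ~16 min and INT2 ~3.7 min later, giving a
fast-phase speed near the injected 1900 nt/min. Loss times are quantized
to the burst clock (5-min spacing in wild type), which is why the
earliest-anchor speed reads 68 rather than 82 nt/min at this burst
spacing, and the small-cohort delay overshoots the injected 10-min lag.
`res$mobility$yku70` holds the per-burst diffusion series, which dips to
well under 100 % of the uncut reference during early resection and
recovers later.

The same stages are scriptable from a shell via the thin CLI in
`inst/scripts/resectrack` (`simulate`, `detect`, `track`, `quantify`,
`msd`, `kinetics`, `run`), e.g.

```sh
Rscript inst/scripts/resectrack run --presets wt,yku70 --cells 10 \
    --seed 1 --out out/
```

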