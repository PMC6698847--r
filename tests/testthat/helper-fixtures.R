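## shared helpers for the test suite

## trapezoid rule on an arbitrary grid
tz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

## central moments of a (time, signal) curve
curve_moment <- function(t, s, order, center = NULL) {
  area <- tz(t, s)
  mu <- if (is.null(center)) tz(t, t * s) / area else center
  tz(t, (t - mu)^order * s) / area
}

## coarse fixture used throughout: laboratory module, synthetic IEX
## isotherm, 8/8/12/8/8 grid
test_spec <- function(...) fixture_spec(resolution = c(8L, 8L, 12L, 8L, 8L),
                                        ...)

## a single-module load schedule at a constant modifier level
simple_load <- function(duration_cv, flow_cv, conc, modifier = 0.02) {
  process_schedule(operating_step("load", duration_cv, flow_cv,
                                  inlet = conc,
                                  modifier_start = modifier))
}

## identifiable synthetic batch-isotherm design: concentration-ratio-varied
## feeds including concentrated purified stocks, membrane stack in the bath
ratio_varied_feeds <- function()
  rbind(c(5, 0.5, 0.5), c(1, 3, 0.5), c(1, 0.5, 3), c(4, 2, 2),
        c(25, 0, 0), c(0.5, 30, 0), c(0.5, 0, 20))
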