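## Quality-control reporting: trace/retrace agreement, deflection and IR
## phase magnitudes, and a rendered panel of maps with row profiles.

#' Quality-control report for an AFM-IR dataset
#'
#' Computes the data-quality metrics used to vet acquisitions: the RMS
#' trace-retrace difference for every channel acquired in both scanning
#' directions (IR Amplitude, IR Phase, PLL Frequency), the mean absolute
#' deflection relative to the setpoint, and the mean absolute IR phase.
#' Optionally renders a panel figure with all channel maps and row profiles
#' overlaying the trace (blue) and retrace (orange) directions along the
#' chosen scan lines. Channels missing the retrace direction get NA metrics
#' but the report is still produced.
#'
#' @param dataset An [AFMIRDataset-class].
#' @param profileRows Integer scan-line indices for the profiles (default:
#'   one third and two thirds of the map height).
#' @param file Optional PNG path for the rendered panel.
#' @param deflectionSetpointV Deflection setpoint (V).
#' @return List: metrics (named list), profileRows, file.
#' @export
qcReport <- function(dataset, profileRows = NULL, file = NULL,
                     deflectionSetpointV = 0) {
  h <- nrow(mapData(dataset@channels[[1]]))
  if (is.null(profileRows))
    profileRows <- unique(pmax(1L, c(round(h / 3), round(2 * h / 3))))
  both <- c("IRAmplitude", "IRPhase", "PLLFrequency")
  rms <- vapply(both, function(ch) {
    if (hasChannel(dataset, ch, "trace") &&
        hasChannel(dataset, ch, "retrace")) {
      tr <- mapData(getChannel(dataset, ch, "trace"))
      re <- mapData(getChannel(dataset, ch, "retrace"))
      sqrt(mean((tr - re)^2))
    } else NA_real_
  }, numeric(1))
  meanAbsDefl <- if (hasChannel(dataset, "Deflection", "trace"))
    mean(abs(mapData(getChannel(dataset, "Deflection", "trace")) -
               deflectionSetpointV))
  else NA_real_
  meanAbsPhase <- if (hasChannel(dataset, "IRPhase", "trace"))
    mean(abs(mapData(getChannel(dataset, "IRPhase", "trace"))))
  else NA_real_
  metrics <- list(traceRetraceRms = as.list(rms),
                  meanAbsDeflectionV = meanAbsDefl,
                  meanAbsIrPhaseDeg = meanAbsPhase,
                  retraceAvailable = as.list(!is.na(rms)))
  if (!is.null(file))
    .renderQcPanel(dataset, profileRows, file)
  list(metrics = metrics, profileRows = profileRows, file = file)
}

.renderQcPanel <- function(dataset, profileRows, file) {
  chans <- unique(vapply(dataset@channels, function(cm) cm@channel,
                         character(1)))
  n <- length(chans)
  grDevices::png(file, width = 320 * n, height = 640, res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, n), mar = c(2.5, 2.5, 2, 1), mgp = c(1.5, .4, 0))
  for (ch in chans) {
    m <- mapData(getChannel(dataset, ch, "trace"))
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(128),
                    axes = FALSE, main = ch)
    for (r in profileRows)
      graphics::abline(h = 1 - (r - 0.5) / nrow(m), col = "red", lty = 2)
  }
  for (ch in chans) {
    tr <- mapData(getChannel(dataset, ch, "trace"))
    re <- if (hasChannel(dataset, ch, "retrace"))
      mapData(getChannel(dataset, ch, "retrace")) else NULL
    r0 <- profileRows[1]
    graphics::plot(tr[r0, ], type = "l", col = "blue", xlab = "px",
                   ylab = ch, main = sprintf("line %d", r0))
    if (!is.null(re)) graphics::lines(re[r0, ], col = "orange")
    if (length(profileRows) > 1) {
      r1 <- profileRows[2]
      graphics::lines(tr[r1, ], col = "blue", lty = 3)
      if (!is.null(re)) graphics::lines(re[r1, ], col = "orange", lty = 3)
    }
  }
  invisible(file)
}
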