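#' @import ggplot2
NULL

#' OEI saline-versus-DOI scatter with median cross
#'
#' One panel per oddball stimulus; each point is a neuron, the cross marks
#' the per-condition medians, and the diagonal is the identity.
#'
#' @param odd [oddballResponses()] table.
#' @param periods The two plotted periods.
#' @return A ggplot object.
#' @export
plotOEIComparison <- function(odd, periods = c("saline", "doi")) {
  a <- odd[odd$period == periods[1], ]
  b <- odd[odd$period == periods[2], ]
  key <- function(df) paste(df$neuron_id, df$stimulus_id)
  i <- match(key(a), key(b))
  d <- data.frame(stimulus_id = a$stimulus_id, x = a$oei,
                  y = b$oei[i])
  d <- d[is.finite(d$x) & is.finite(d$y), ]
  med <- aggregate(cbind(x, y) ~ stimulus_id, d, median)
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.5, size = 1) +
    geom_point(data = med, colour = "red", shape = 3, size = 4,
               stroke = 1.2) +
    facet_wrap(~stimulus_id, nrow = 1) +
    labs(x = sprintf("OEI (%s)", periods[1]),
         y = sprintf("OEI (%s)", periods[2])) +
    theme_classic()
}

#' Median modulation-index bars for oddballs versus standards
#'
#' Bar height is the median MI per stimulus and role; error bars show the
#' standard error of the mean.
#'
#' @param mi [modulationIndices()] table.
#' @return A ggplot object.
#' @export
plotMIBars <- function(mi) {
  d <- mi[is.finite(mi$mi), ]
  agg <- do.call(rbind, lapply(split(d, list(d$stimulus_id, d$role),
                                     drop = TRUE), function(g)
    data.frame(stimulus_id = g$stimulus_id[1], role = g$role[1],
               median = median(g$mi), se = sd(g$mi) / sqrt(nrow(g)))))
  ggplot(agg, aes(x = .data$stimulus_id, y = .data$median,
                  fill = .data$role)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$median - .data$se,
                      ymax = .data$median + .data$se),
                  position = position_dodge(0.8), width = 0.2) +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "modulation index (DOI vs saline)") +
    theme_classic()
}

#' Fano-factor saline-versus-DOI scatter
#'
#' @param fano [fanoByNeuron()] rows of a single split.
#' @param periods The two plotted periods.
#' @return A ggplot object.
#' @export
plotFanoComparison <- function(fano, periods = c("saline", "doi")) {
  a <- fano[fano$period == periods[1], ]
  b <- fano[fano$period == periods[2], ]
  i <- match(a$neuron_id, b$neuron_id)
  d <- data.frame(x = a$ff_mean, y = b$ff_mean[i])
  d <- d[is.finite(d$x) & is.finite(d$y), ]
  lim <- range(c(d$x, d$y))
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.6, size = 1) +
    annotate("point", x = median(d$x), y = median(d$y), colour = "red",
             shape = 3, size = 4, stroke = 1.2) +
    coord_fixed(xlim = lim, ylim = lim) +
    labs(x = sprintf("Fano factor (%s)", periods[1]),
         y = sprintf("Fano factor (%s)", periods[2])) +
    theme_classic()
}
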