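#' Rate raster of a network record
#'
#' Heatmap of the recorded output rates (neuron index vs time), the
#' standard display of sequence propagation and place-field formation.
#'
#' @param record A `"network_record"` (or any list with `time` and `z`).
#' @param max_points Downsample the time axis to at most this many columns.
#' @return A ggplot object.
#' @export
plot_rate_raster <- function(record, max_points = 2000) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_rate_raster requires ggplot2")
  if (is.null(record$z) || length(record$z) == 0)
    stop("plot_rate_raster: record contains no rate traces")
  z <- record$z
  keep <- unique(round(seq(1, ncol(z), length.out = min(max_points,
                                                        ncol(z)))))
  df <- data.frame(
    time_s = rep(record$time[keep] / 1000, each = nrow(z)),
    neuron = rep(seq_len(nrow(z)), length(keep)),
    rate_hz = as.vector(z[, keep, drop = FALSE]) * 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$neuron,
                                   fill = .data$rate_hz)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rate (Hz)") +
    ggplot2::labs(x = "time (s)", y = "neuron")
}

#' Group-wise weight trajectories of a single-cell record
#'
#' Mean and standard deviation of the synaptic weights of each input group
#' over the recorded snapshots, for both compartments.
#'
#' @param record A `"cell_record"` from [simulate_cells()].
#' @param cell Cell index to display.
#' @return A ggplot object.
#' @export
plot_weight_trajectories <- function(record, cell = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_weight_trajectories requires ggplot2")
  sn <- record$snapshots
  if (length(sn$time) == 0)
    stop("plot_weight_trajectories: record contains no weight snapshots")
  rows <- list()
  for (side in c("som", "dnd")) {
    w <- sn[[paste0("w_", side)]]
    groups <- record[[paste0("groups_", side)]]
    for (g in names(groups)) {
      idx <- groups[[g]]
      rows[[paste(side, g)]] <- data.frame(
        time_s = sn$time / 1000, compartment = side, group = g,
        mean = apply(w[cell, idx, , drop = FALSE], 3, mean),
        sd = apply(w[cell, idx, , drop = FALSE], 3, stats::sd))
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                   color = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = "time (s)", y = "synaptic weight")
}

#' Export a network record to CSV files
#'
#' Writes the rate traces (long format: time, neuron, rate), the behavior
#' (time, position, moving, arm), and the final weight matrices as plain
#' CSV files, for small records.
#'
#' @param record A `"network_record"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_record_csv <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  f <- file.path(dir, "behavior.csv")
  utils::write.csv(data.frame(time_ms = record$time, pos = record$pos,
                              moving = record$moving, arm = record$arm),
                   f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(dir, "rates.csv")
  zt <- as.data.frame(t(record$z))
  names(zt) <- paste0("n", seq_len(nrow(record$z)))
  utils::write.csv(cbind(time_ms = record$time, zt), f, row.names = FALSE)
  paths <- c(paths, f)
  for (nm in c("w_som", "w_dnd", "v_dnd")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(record[[nm]], f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
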