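#' Render static result plots for a run
#'
#' Writes four PNG files per analysed offspring/chromosome combination:
#' the GoO scatter (one row per parental side, points coloured by
#' scaffold, with seeded y-jitter to relieve overplotting), the PD
#' profile, the CCS run plot (runs below the threshold drawn in a
#' distinct noise colour) and the informative-call density track.
#' Combinations without informative calls get placeholder images
#' annotated "no informative SNPs". Plotting failures are logged and
#' never abort the run.
#'
#' @param bundle result of [run_analysis()]
#' @param out_dir output directory
#' @param jitter_seed seed for the GoO scatter jitter (plots are
#'   deterministic given this seed)
#' @return invisibly, the paths of the files written
#' @export
render_plots <- function(bundle, out_dir, jitter_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (tag in names(bundle$details)) {
    det <- bundle$details[[tag]]
    paths <- try(plot_one_combination(det, bundle, tag, out_dir,
                                      jitter_seed),
                 silent = TRUE)
    if (inherits(paths, "try-error")) {
      message("plotting failed for ", tag, ": ",
              attr(paths, "condition")$message)
    } else {
      written <- c(written, paths)
    }
  }
  invisible(written)
}

plot_one_combination <- function(det, bundle, tag, out_dir, jitter_seed) {
  goo <- det$goo
  ccs_threshold <- bundle$config$ccs_threshold %||% 50L
  save_png <- function(name, p) {
    path <- file.path(out_dir, sprintf("%s_%s.png", name, tag))
    ggplot2::ggsave(path, p, width = 9, height = 3.2, dpi = 120,
                    device = grDevices::png)
    path
  }
  placeholder <- function(label) {
    ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no informative SNPs") +
      ggplot2::labs(title = label) +
      ggplot2::theme_void()
  }

  both <- do.call(rbind, lapply(c("paternal", "maternal"), function(s) {
    if (nrow(goo[[s]])) cbind(goo[[s]], side = s) else NULL
  }))
  p_goo <- if (is.null(both) || !nrow(both)) {
    placeholder(paste("GoO:", tag))
  } else {
    set.seed(jitter_seed)
    both$y <- as.integer(both$side == "paternal") +
      stats::runif(nrow(both), -0.3, 0.3)
    ggplot2::ggplot(both, ggplot2::aes(
      x = .data$chrom_pos / 1e6, y = .data$y,
      colour = .data$scaffold, shape = .data$origin)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.6) +
      ggplot2::scale_y_continuous(breaks = c(0, 1),
                                  labels = c("maternal", "paternal")) +
      ggplot2::labs(x = "chromosomal position (Mb)", y = NULL,
                    title = paste("Grandparent-of-origin:", tag)) +
      ggplot2::theme_minimal()
  }

  p_pd <- if (is.null(det$pd_profile) || !nrow(det$pd_profile)) {
    placeholder(paste("PD:", tag))
  } else {
    ggplot2::ggplot(det$pd_profile, ggplot2::aes(
      x = .data$midpoint_bp / 1e6, y = .data$D)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~side, ncol = 1) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "chromosomal position (Mb)",
                    y = "|proportion difference|",
                    title = paste("PD profile:", tag)) +
      ggplot2::theme_minimal()
  }

  p_ccs <- if (is.null(det$ccs_runs) || !nrow(det$ccs_runs)) {
    placeholder(paste("CCS:", tag))
  } else {
    runs <- det$ccs_runs
    runs$status <- ifelse(runs$ccs >= ccs_threshold, runs$origin, "noise")
    ggplot2::ggplot(runs, ggplot2::aes(
      x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
      y = .data$ccs, yend = .data$ccs, colour = .data$status)) +
      ggplot2::geom_segment(linewidth = 1) +
      ggplot2::scale_colour_manual(values = c(
        GF = "#e08214", GM = "#8073ac", noise = "black")) +
      ggplot2::facet_wrap(~side, ncol = 1) +
      ggplot2::labs(x = "chromosomal position (Mb)", y = "CCS",
                    title = paste("CCS runs:", tag)) +
      ggplot2::theme_minimal()
  }

  dens <- det$density
  dens_long <- rbind(
    data.frame(mid = (dens$bin_start + dens$bin_end) / 2e6,
               count = dens$paternal, side = "paternal"),
    data.frame(mid = (dens$bin_start + dens$bin_end) / 2e6,
               count = dens$maternal, side = "maternal"))
  p_dens <- if (!sum(dens_long$count)) {
    placeholder(paste("density:", tag))
  } else {
    ggplot2::ggplot(dens_long, ggplot2::aes(
      x = .data$mid, y = .data$count, fill = .data$side)) +
      ggplot2::geom_col(position = "dodge", width = 0.9) +
      ggplot2::labs(x = "chromosomal position (Mb)",
                    y = "informative calls / bin",
                    title = paste("Informative-call density:", tag)) +
      ggplot2::theme_minimal()
  }

  c(save_png("goo", p_goo), save_png("pd", p_pd),
    save_png("ccs", p_ccs), save_png("density", p_dens))
}
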