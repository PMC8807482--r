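# Presentation-only figures, derived strictly from the computed profiles and
# comparison objects. Requires ggplot2 (Suggests); callers guard with
# requireNamespace.

profile_frame <- function(profiles, sheet) {
  mode <- names(profiles)[1]
  do.call(rbind, lapply(names(profiles[[mode]]), function(id) {
    p <- profiles[[mode]][[id]]
    i <- match(id, sheet$repertoire_id)
    data.frame(repertoire_id = id, group = sheet$group[i],
               time_point = sheet$time_point[i], isotype = sheet$isotype[i],
               normalized_diversity = p$normalized_diversity,
               mean_mutations = p$mean_mutations, stringsAsFactors = FALSE)
  }))
}

#' Diversity bar chart per repertoire
#' @param profiles profiles list from [run_pipeline()] (one clonotype mode).
#' @param sheet sample sheet data.frame.
#' @return A ggplot object.
#' @export
plot_diversity <- function(profiles, sheet) {
  df <- profile_frame(profiles, sheet)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$isotype,
                                   y = .data$normalized_diversity,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$time_point) +
    ggplot2::labs(y = "clonotypes / reads", x = NULL) +
    ggplot2::theme_minimal()
}

#' V-gene usage bar chart
#' @param profiles profiles list from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_v_usage <- function(profiles) {
  mode <- names(profiles)[1]
  df <- do.call(rbind, lapply(names(profiles[[mode]]), function(id) {
    u <- unlist(profiles[[mode]][[id]]$v_usage)
    data.frame(repertoire_id = id, v_gene = names(u), frequency = unname(u),
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v_gene, y = .data$frequency)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "fraction of clonotypes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

pipeline_figures <- function(profiles, cmp, sheet, fdir) {
  paths <- character(0)
  p1 <- file.path(fdir, "diversity.png")
  ggplot2::ggsave(p1, plot_diversity(profiles, sheet), width = 7, height = 4,
                  dpi = 120)
  p2 <- file.path(fdir, "v_usage.png")
  ggplot2::ggsave(p2, plot_v_usage(profiles), width = 7, height = 4, dpi = 120)
  p3 <- file.path(fdir, "tree.png")
  grDevices::png(p3, width = 800, height = 600)
  plot(cmp$tree$phylo, cex = 0.8)
  grDevices::dev.off()
  c(p1, p2, p3)
}
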