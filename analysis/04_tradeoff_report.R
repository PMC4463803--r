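#!/usr/bin/env Rscript
# Synthesis over the screening and variance-based runs: the yield/protein
# antagonism, rank agreement between the two sensitivity methods, and
# optional heat-map figures. Requires the outputs of 02 and 03.

library(wheatsens)

stopifnot(file.exists("results/morris_stats.csv"),
          file.exists("results/efast_indices.csv"))
mo <- read.csv("results/morris_stats.csv")
signs <- read.csv("results/oat_signs.csv")
ef <- read.csv("results/efast_indices.csv")
dir.create("results", showWarnings = FALSE)

## yield/protein sign antagonism among influential factors
hm <- build_heatmaps(mo[mo$output %in% c("grain_dm", "gpc"), ],
                     value = "mu_star", rescale = TRUE, signs = signs)
key <- paste(hm$factor, hm$site, hm$n_treatment)
v_gy <- setNames(hm$value_scaled[hm$output == "grain_dm"],
                 key[hm$output == "grain_dm"])
v_gpc <- setNames(hm$value_scaled[hm$output == "gpc"],
                  key[hm$output == "gpc"])
common <- intersect(names(v_gy), names(v_gpc))
infl <- common[abs(v_gy[common]) > 0.1 & abs(v_gpc[common]) > 0.1]
cat(sprintf("Influential factor-scenario pairs: %d; opposite GY/GPC signs: %.0f%%\n",
            length(infl), 100 * mean(v_gy[infl] * v_gpc[infl] < 0)))
same <- infl[v_gy[infl] * v_gpc[infl] >= 0]
if (length(same))
  cat("Same-sign exceptions:", paste(same, collapse = "; "), "\n")

## rank agreement between the two methods (GY, per site x N)
agree <- do.call(rbind, lapply(split(ef, ef[c("site", "n_treatment")]),
  function(d) {
    d <- d[d$output == "grain_dm", ]
    if (!nrow(d)) return(NULL)
    m <- mo[mo$output == "grain_dm" & mo$site == d$site[1] &
              mo$n_treatment == d$n_treatment[1], ]
    m_med <- tapply(m$mu_star, m$factor, median)
    e_med <- tapply(d$s_ti, d$factor, median)
    shared <- intersect(names(m_med), names(e_med))
    data.frame(site = d$site[1], n_treatment = d$n_treatment[1],
               spearman = cor(rank(m_med[shared]), rank(e_med[shared])))
  }))
write.csv(agree, "results/method_rank_agreement.csv", row.names = FALSE)
print(agree, row.names = FALSE)

## optional heat-map figure
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  hm_all <- build_heatmaps(mo, value = "mu_star", rescale = TRUE,
                           signs = signs)
  hm_all$factor <- factor(hm_all$factor, levels = rev(parameter_table()$name))
  gg <- ggplot(hm_all, aes(interaction(site, n_treatment), factor,
                           fill = value_scaled)) +
    geom_tile() +
    facet_grid(. ~ output) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         limits = c(-1, 1), name = "signed\nrescaled mu*") +
    labs(x = "site x N treatment", y = NULL) +
    theme_minimal(base_size = 7) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
  ggsave("results/morris_heatmap.png", gg, width = 11, height = 9, dpi = 150)
  cat("Wrote results/morris_heatmap.png\n")
}
cat("Wrote results/method_rank_agreement.csv\n")
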