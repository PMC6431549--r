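#!/usr/bin/env Rscript
# Worked example on the published Sierra Tarahumara accounting tables:
# per-epoch shares, net changes 1990-2005-2017, and the conversion of the
# projected 2050 shares into hectare changes on the fixed footprint.

suppressPackageStartupMessages(library(lulcsim))
dir.create("results/published", recursive = TRUE, showWarnings = FALSE)

areas <- tarahumara_areas()
at <- area_table_from_areas(areas)
write.csv(at, "results/published/area_table.csv", row.names = FALSE)

cat("Class shares (%):\n")
print(reshape(at[, c("class", "epoch", "share_pct")],
              idvar = "class", timevar = "epoch", direction = "wide"))

nc_all <- do.call(rbind, lapply(
  list(c(1990, 2005), c(2005, 2017), c(1990, 2017)),
  function(p) {
    d <- net_change(at, p[1], p[2])
    d$period <- paste(p, collapse = "-")
    d
  }))
write.csv(nc_all, "results/published/net_change.csv", row.names = FALSE)
cat("\nNet change (ha):\n")
print(nc_all)

# hectare change implied by the projected 2050 shares, per scenario
footprint <- sum(areas$area_ha[areas$epoch == 1990])
sh <- tarahumara_projected_shares()
scen <- do.call(rbind, lapply(c(s = "2050s", o = "2050o", p = "2050p"),
                              function(ep) {
  d <- scenario_report(sh[sh$epoch %in% c("2017", ep), ], footprint)
  d$scenario <- ep
  d
}))
write.csv(scen, "results/published/scenario_change.csv", row.names = FALSE)
cat(sprintf("\nFootprint: %.1f ha; stationary PF change: %.2f ha\n",
            footprint,
            scen$change_ha[scen$class == "PF" & scen$scenario == "2050s"]))
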