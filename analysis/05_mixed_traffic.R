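#!/usr/bin/env Rscript
# Step 5 — mixed-traffic assessment.
#
# The car and truck ASI models are blended by the truck proportion w and
# the matching severity cut points shrink linearly in w; tabulated here
# over w = 0, 0.1, ..., 1 together with a worked example case.

library(treecrash)

ws <- seq(0, 1, by = 0.1)
example <- data.frame(speed_kmh = 80, road_type = "straight",
                      radius_m = Inf, diameter_cm = 25, spacing_m = 5,
                      vehicle = "car")
tab <- do.call(rbind, lapply(ws, function(w) {
  thr <- mixed_thresholds(w)
  asi <- predict_asi_mixed(example, w)
  data.frame(w = w, b2 = thr$b2, b3 = thr$b3,
             asi_example = asi,
             grade_example = as.character(assign_grade(asi, thr)))
}))

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/mixed_thresholds.csv", row.names = FALSE)
cat("wrote results/mixed_thresholds.csv\n")
print(tab)
cat("\nexample (V=80 km/h, straight, D=25 cm, L=5 m): the blended ASI is\n",
    "nearly flat in w here, but the cut points shrink with the truck\n",
    "share, so the same physical scenario grades more severe on a\n",
    "truck-heavy road.\n")
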