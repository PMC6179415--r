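#!/usr/bin/env Rscript
# Assemble the phase-labeled protocol time courses: baseline-normalized
# channel intensities, the optical redox ratio and the two reflectance
# ratio metrics; aggregate to group mean +/- SD; characterize insult and
# reperfusion 10-90% transition times of the hypoxia group.

suppressPackageStartupMessages(library(langflim))

datasets <- readRDS("scratch/datasets.rds")

tc <- do.call(rbind, lapply(datasets, protocol_timecourses))
utils::write.csv(tc, "results/timecourses_long.csv", row.names = FALSE)
gs <- summarize_groups(tc)
utils::write.csv(gs, "results/group_summary.csv", row.names = FALSE)

level <- function(g, m, t0, t1) {
  s <- gs[gs$group == g & gs$metric == m & gs$time_s >= t0 & gs$time_s < t1, ]
  mean(s$mean)
}
message("insult-plateau levels (group mean over the last 3 min of insult, baseline = 1):")
for (g in names(datasets)) {
  message(sprintf("  %-18s nCH2 %.2f | nCH4 %.2f | RR %.3f | ox %.2f | cytc %.2f",
                  g, level(g, "nCH2", 450, 630), level(g, "nCH4", 450, 630),
                  level(g, "RR", 450, 630), level(g, "ox_ratio", 450, 630),
                  level(g, "cytc_ratio", 450, 630)))
}

# 10-90% transition times of the hypoxia intensity response
trans <- list()
for (met in c("nCH2", "nCH4", "RR")) {
  m <- gs[gs$group == "hypoxia" & gs$metric == met, ]
  ins <- m$time_s >= 180 & m$time_s < 630
  rep_ <- m$time_s >= 630
  trans[[met]] <- c(
    insult_s = as.numeric(transition_time_10_90(m$mean[ins], m$time_s[ins])),
    reperfusion_s = as.numeric(transition_time_10_90(m$mean[rep_], m$time_s[rep_]))
  )
  message(sprintf("hypoxia %s 10-90%% transition: insult %.0f s, reperfusion %.0f s",
                  met, trans[[met]]["insult_s"], trans[[met]]["reperfusion_s"]))
}
utils::write.csv(
  data.frame(metric = names(trans), do.call(rbind, trans)),
  "results/transition_times.csv", row.names = FALSE)

message("reperfusion recovers more slowly than the insult develops: ",
        all(vapply(trans, function(x) x["reperfusion_s"] > x["insult_s"], logical(1))))
message("time-course tables written under results/")
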