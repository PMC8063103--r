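#!/usr/bin/env Rscript

# Step 4: classifier validation on synthetic line scans.
#
# Generates line-scan matrices with prescribed phenotypes (full propagation,
# beat-to-beat alternation, central attenuation, both, and a repolarization-
# failure action potential train) across noise levels and seeds, classifies
# each, and tabulates the confusion matrix, which must be diagonal.
#
# Writes results/synthetic/confusion.csv.

suppressMessages(library(atriawave))

att_sil <- rep(1, 18); att_sil[2:17] <- 0.05
make_spec <- function(kind, seed, noise)
  switch(kind,
    normal = trace_spec(n_beats = 10, seed = seed, noise_sd = noise),
    alternans = trace_spec(n_beats = 10, alternans_ratio = 0.8, seed = seed,
                           noise_sd = noise),
    silencing = trace_spec(n_beats = 10, attenuation = att_sil, seed = seed,
                           noise_sd = noise),
    alternans_and_silencing = trace_spec(n_beats = 10, attenuation = att_sil,
                                         alternans_ratio = 0.8, seed = seed,
                                         noise_sd = noise))

kinds <- c("normal", "alternans", "silencing", "alternans_and_silencing")
rows <- list()
for (kind in kinds) for (seed in 1:5) for (noise in c(0, 0.004)) {
  res <- gen_linescan(make_spec(kind, seed, noise))
  got <- as.character(classify(res)$category)
  rows[[length(rows) + 1]] <- data.frame(truth = kind, predicted = got,
                                         seed = seed, noise_sd = noise)
}
# repolarization-failure AP train on top of a normal line scan -> "other"
# (recording starts in diastole; diastolic potential then sticks at -50 mV)
for (seed in 1:5) {
  res <- gen_linescan(make_spec("normal", seed, 0))
  tr <- gen_ap_train(n_beats = 10, apd = 100, shape = "triangular")
  v <- approx(tr$t, tr$V, xout = (res$t + 900) %% 10000, rule = 2)$y
  v[res$t >= 300 & v <= -70] <- -50
  res$V <- v
  rows[[length(rows) + 1]] <- data.frame(truth = "other",
                                         predicted = as.character(classify(res)$category),
                                         seed = seed, noise_sd = 0)
}
df <- do.call(rbind, rows)
conf <- as.data.frame.matrix(table(df$truth, df$predicted))
print(conf)
message(sprintf("accuracy: %.1f%%", 100 * mean(df$truth == df$predicted)))

dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)
write.csv(cbind(truth = rownames(conf), conf),
          "results/synthetic/confusion.csv", row.names = FALSE)
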