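#!/usr/bin/env Rscript
# Stage 1: are the flower colours detectable and distinguishable in fly
# vision? Maps every synthetic capitulum into the categorical opponency
# plane against each soil background, writes the points table, the
# centroid-distance matrix, and Welch tests of native- vs foreign-soil
# detectability.

suppressMessages(library(daisyfly))
dir.create("results", showWarnings = FALSE)
spectra <- read_spectra_csv("results/data/spectra.csv", "reflectance")

grid <- wl_grid(300, 700, 1)
rec <- receptor_set(grid)
ill <- d65_illuminant(grid)
spectra <- lapply(spectra, resample, grid = grid)

species <- c("D_sinuata", "U_cakilefolia", "D_pluvialis", "U_speciosa")
soils <- c(pale = "pale_soil", red = "red_soil")
th <- threshold_map()

rows <- list()
clouds <- list()
for (soil in names(soils)) {
  for (sp in species) {
    pts <- lapply(1:5, function(i) {
      bg <- spectra[[paste(soils[[soil]], i, sep = "_")]]
      fl <- spectra[[paste(sp, i, sep = "_")]]
      troje_point(quantum_catch(fl, ill, rec), quantum_catch(bg, ill, rec))
    })
    clouds[[paste(sp, soil, sep = ".")]] <- species_cloud(sp, pts)
    for (i in seq_along(pts)) {
      p <- pts[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, soil = soil, image = i, x = p$x, y = p$y,
        quadrant = p$quadrant, dist_origin = p$dist_origin,
        verdict = detectability_verdict(p, th))
    }
  }
}
points_tab <- do.call(rbind, rows)
write.csv(points_tab, "results/vision_points.csv", row.names = FALSE)

# centroid-distance matrices, one per soil
for (soil in names(soils)) {
  cl <- clouds[paste(species, soil, sep = ".")]
  D <- outer(seq_along(cl), seq_along(cl),
             Vectorize(function(i, j) centroid_distance(cl[[i]], cl[[j]])))
  dimnames(D) <- list(species, species)
  write.csv(round(D, 4), sprintf("results/centroid_distances_%s.csv", soil))
  cat(sprintf("[%s soil] orange-vs-white centroid distances: %s\n", soil,
              paste(sprintf("%s-%s %.3f",
                            rep(c("D_sinuata", "U_cakilefolia"), each = 2),
                            rep(c("D_pluvialis", "U_speciosa"), 2),
                            c(D["D_sinuata", "D_pluvialis"],
                              D["D_sinuata", "U_speciosa"],
                              D["U_cakilefolia", "D_pluvialis"],
                              D["U_cakilefolia", "U_speciosa"])),
                    collapse = ", ")))
}

# Welch tests: is each species more detectable on its native soil?
native <- c(D_sinuata = "pale", U_cakilefolia = "pale",
            D_pluvialis = "red", U_speciosa = "red")
cat("\nNative- vs foreign-soil detectability (Welch's t):\n")
welch_rows <- lapply(species, function(sp) {
  d_nat <- points_tab$dist_origin[points_tab$species == sp &
                                    points_tab$soil == native[[sp]]]
  d_for <- points_tab$dist_origin[points_tab$species == sp &
                                    points_tab$soil != native[[sp]]]
  w <- welch_t(d_nat, d_for)
  cat(sprintf("  %-14s t = %6.2f, df = %.2f, p = %.3f\n", sp, w$t, w$df, w$p))
  data.frame(species = sp, t = w$t, df = w$df, p = w$p)
})
write.csv(do.call(rbind, welch_rows), "results/detectability_welch.csv",
          row.names = FALSE)

n_det <- sum(points_tab$verdict == "detectable")
cat(sprintf("\n%d/%d points exceed their quadrant's discrimination threshold; %d in quadrants without a threshold (verdict unknown).\n",
            n_det, nrow(points_tab),
            sum(points_tab$verdict == "unknown")))
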