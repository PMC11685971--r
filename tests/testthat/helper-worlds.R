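# Small synthetic worlds used across tests: two cities, 3 km AOIs, three
# months per year. Kept small so each test file regenerates what it needs.

small_world_config <- function(seed = 1, ...) {
  world_config(
    n_cities = 2,
    aoi_size_km = 3,
    pop_model = list(total_range = c(1.5e4, 3e4), n_hotspots = 2,
                     hotspot_sd_frac = 0.18, floor_frac = 0.10),
    link_model = list(a = 0.03, b = 1, noise = "poisson"),
    image_model = list(years = c(2019, 2020, 2022), months = 4:6,
                       per_month_lambda = 1.5, side_frac_range = c(0.75, 1),
                       gsd_levels = c(0.3, 0.4, 0.5),
                       gsd_probs = c(0.35, 0.35, 0.30),
                       off_nadir_range = c(5, 40), sun_elev_range = c(20, 60),
                       cloud_beta = c(0.6, 8), snow_prob_winter = 0.3,
                       snow_prob_other = 0.02),
    seed = seed,
    ...)
}

# single fully-covered fine cell + rectangle footprint, for link-model checks
one_cell_image <- function(people, cloud_frac = 0, cell_m = 100) {
  list(image = list(image_id = "img1", aoi_id = "a", cloud_frac = cloud_frac,
                    footprint = rect_poly(-50, -50, 150, 150)),
       cells = data.frame(aoi_id = "a", x = cell_m / 2, y = cell_m / 2,
                          cell_m = cell_m, people = people))
}

# baseline table with an exactly proportional people = k * cars link
proportional_baseline <- function(n_cells = 30, k = 50, seed = 7) {
  set.seed(seed)
  cars <- round(runif(n_cells, 1, 40), 3)
  data.frame(aoi_id = "cityA",
             cell_id = sprintf("cityA_%03d", seq_len(n_cells)),
             people = k * cars, cars = cars)
}
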