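#' Default skin-cancer scenario configuration
#'
#' The built-in scenario: a 6 mm cube of normal tissue centred in a 10 mm
#' air domain, an oblate-spheroid tumour (diameter 1 mm, height 0.5 mm)
#' with its top 1 mm below the skin surface, and a 1 W, 3 mm-radius disc
#' source in the air above, emitting straight down. Optical coefficients
#' (cm^-1): normal tissue 0.7/36.7, tumour 2.3/21.2, gold nanorods
#' 12/1.2 (the fitted infusion, scattering:absorption = 0.1); the
#' GNR-infused tumour is their component-wise sum, 14.3/22.4.
#'
#' @param gnr logical: infuse the tumour with gold nanorods (TRUE) or run
#'   the control (FALSE).
#' @param grid_preset "fast" (101^3) or "full" (201^3).
#' @param packets transport packet count.
#' @param seed RNG seed.
#' @param power source power (W).
#' @param duration heating time (s).
#' @param record_interval snapshot cadence (s).
#' @return a nested configuration list (see [loadConfig()]).
#' @export
defaultConfig <- function(gnr = TRUE, grid_preset = c("fast", "full"),
                          packets = 1e7, seed = 1, power = 1,
                          duration = 600, record_interval = 20) {
  grid_preset <- match.arg(grid_preset)
  n <- if (grid_preset == "fast") 101L else 201L
  list(
    materials = list(
      air = list(mu_a = 0, mu_s = 0, g = 0, n = 1),
      normal_tissue = list(mu_a = 0.7, mu_s = 36.7, g = 0.9, n = 1.38),
      tumour = list(mu_a = 2.3, mu_s = 21.2, g = 0.9, n = 1.38),
      gold_nanorods = list(mu_a = 12, mu_s = 1.2, g = 0.9, n = 1.38),
      tumour_gnr = list(mu_a = 14.3, mu_s = 22.4, g = 0.9, n = 1.38)),
    ambient = "air",
    entities = list(
      list(label = "flesh", shape = "cuboid", center = c(0, 0, 0),
           size = c(6, 6, 6), material = "normal_tissue", priority = 1),
      list(label = "tumour", shape = "ellipsoid", center = c(0, 0, 1.75),
           semi_axes = c(0.5, 0.5, 0.25),
           material = if (gnr) "tumour_gnr" else "tumour", priority = 2)),
    source = list(center = c(0, 0, 4), radius = 3, n_fan = 16,
                  power = power, direction = c(0, 0, -1)),
    grid = list(extent = c(-5, 5), n_cells = n),
    transport = list(packets = packets, seed = seed, w_min = 1e-4,
                     p_survive = 0.1),
    heat = list(duration = duration, record_interval = record_interval,
                boundary = "clamped-sides",
                params = list(rho = 1079, c = 3540, k = 0.53, rho_b = 1060,
                              c_b = 3617, w_b = 0.01, T_a = 37)),
    dose = list(r_above = 0.5, r_below = 0.25, anchor_minutes = 120,
                anchor_fraction = 0.1))
}

#' Load and validate a run configuration
#'
#' JSON is the primary format; files ending in .yml/.yaml are parsed with
#' the yaml package if installed. Missing optional blocks get the
#' defaults of [defaultConfig()]; validation failures name the offending
#' field.
#'
#' @param path configuration file.
#' @return validated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::yaml.load_file(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE)
  }
  validateConfig(cfg)
}

#' @rdname loadConfig
#' @param cfg configuration list.
#' @export
validateConfig <- function(cfg) {
  def <- defaultConfig()
  for (blk in c("dose")) if (is.null(cfg[[blk]])) cfg[[blk]] <- def[[blk]]
  for (fld in names(def$dose))
    if (is.null(cfg$dose[[fld]])) cfg$dose[[fld]] <- def$dose[[fld]]
  if (is.null(cfg$heat)) cfg$heat <- def$heat
  if (is.null(cfg$heat$params)) cfg$heat$params <- def$heat$params
  if (is.null(cfg$heat$record_interval))
    cfg$heat$record_interval <- def$heat$record_interval
  if (is.null(cfg$heat$boundary)) cfg$heat$boundary <- def$heat$boundary
  if (is.null(cfg$transport)) stop("config is missing the 'transport' block")
  if (is.null(cfg$transport$seed))
    stop("config field 'transport.seed' is required")
  if (is.null(cfg$transport$w_min)) cfg$transport$w_min <- 1e-4
  if (is.null(cfg$transport$p_survive)) cfg$transport$p_survive <- 0.1
  if (is.null(cfg$materials) || !length(cfg$materials))
    stop("config field 'materials' is required")
  for (nm in names(cfg$materials)) {
    m <- cfg$materials[[nm]]
    for (fld in c("mu_a", "mu_s"))
      if (is.null(m[[fld]]) || m[[fld]] < 0)
        stop(sprintf("config field 'materials.%s.%s' must be >= 0", nm, fld))
    if (is.null(m$g)) cfg$materials[[nm]]$g <- 0.9
    if (is.null(m$n)) cfg$materials[[nm]]$n <- 1.38
  }
  if (is.null(cfg$ambient)) cfg$ambient <- "air"
  if (!cfg$ambient %in% names(cfg$materials))
    stop("config field 'ambient' names an undefined material: ", cfg$ambient)
  ents <- cfg$entities
  if (is.data.frame(ents)) ents <- split(ents, seq_len(nrow(ents)))
  for (i in seq_along(ents)) {
    e <- as.list(ents[[i]])
    if (is.null(e$material) || !e$material %in% names(cfg$materials))
      stop(sprintf("config field 'entities[%d].material' is undefined: %s",
                   i, e$material))
    if (is.null(e$priority))
      stop(sprintf("config field 'entities[%d].priority' is required", i))
  }
  if (is.null(cfg$source$power) || cfg$source$power <= 0)
    stop("config field 'source.power' must be positive")
  if (is.null(cfg$grid$n_cells))
    stop("config field 'grid.n_cells' is required")
  cfg
}

#' @rdname loadConfig
#' @export
saveConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a scene from a configuration
#'
#' @param cfg configuration list from [loadConfig()] or
#'   [defaultConfig()].
#' @return a [Scene-class].
#' @export
buildScene <- function(cfg) {
  cfg <- validateConfig(cfg)
  mats <- lapply(names(cfg$materials), function(nm) {
    m <- cfg$materials[[nm]]
    opticalMaterial(nm, m$mu_a, m$mu_s, m$g, m$n)
  })
  names(mats) <- names(cfg$materials)
  ents <- cfg$entities
  if (is.data.frame(ents)) ents <- split(ents, seq_len(nrow(ents)))
  entities <- lapply(seq_along(ents), function(i) {
    e <- as.list(ents[[i]])
    flat <- function(x) as.numeric(unlist(x))
    if (identical(e$shape, "cuboid")) {
      entity(e$label, "cuboid", e$material, e$priority,
             center = flat(e$center), size = flat(e$size))
    } else if (identical(e$shape, "ellipsoid")) {
      entity(e$label, "ellipsoid", e$material, e$priority,
             center = flat(e$center), semi_axes = flat(e$semi_axes))
    } else if (identical(e$shape, "stl") || identical(e$shape, "mesh")) {
      entity(e$label, "mesh", e$material, e$priority,
             mesh = readSTL(e$path))
    } else stop("unknown entity shape: ", e$shape)
  })
  src <- makeDiscSource(as.numeric(unlist(cfg$source$center)),
                        cfg$source$radius,
                        n_fan = if (is.null(cfg$source$n_fan)) 16L
                                else cfg$source$n_fan,
                        power = cfg$source$power,
                        direction = if (is.null(cfg$source$direction))
                          c(0, 0, -1)
                        else as.numeric(unlist(cfg$source$direction)))
  grid <- voxelGridDef(as.numeric(unlist(cfg$grid$extent)),
                       cfg$grid$n_cells)
  scene(mats, entities, src, grid, ambient = cfg$ambient)
}

#' Bioheat parameters from a configuration
#'
#' @param cfg configuration list.
#' @return a [BioheatParams-class].
#' @export
configBioheatParams <- function(cfg) {
  p <- cfg$heat$params
  bioheatParams(rho = p$rho, c = p$c, k = p$k, rho_b = p$rho_b, c_b = p$c_b,
                w_b = p$w_b, T_a = p$T_a)
}
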