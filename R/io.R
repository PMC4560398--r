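# File formats: YAML run configuration, hex-text genotype archives with a
# JSON manifest, CSV fitness tables and trial logs. Everything is plain
# text and round-trips byte-identically (write -> read -> write).

GENOTYPE_MAP_VERSION <- "1"

#' Hex-text encoding of a genotype
#'
#' Bytes are the 8-bit parameter groups, MSB first, written as lowercase hex
#' (172 characters for the 86-parameter genotype).
#'
#' @param bits Integer 0/1 vector of length 688.
#' @return Hex string.
#' @export
bits_to_hex <- function(bits) {
  paste(sprintf("%02x", genotype_bytes(bits)), collapse = "")
}

#' @rdname bits_to_hex
#' @param hex Hex string from [bits_to_hex()].
#' @return Integer 0/1 vector of length 688.
#' @export
hex_to_bits <- function(hex) {
  stopifnot(nchar(hex) == 2 * N_PARAMS)
  b <- strtoi(substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)),
              base = 16L)
  as.integer(vapply(b, function(v) as.integer(intToBits(v)[8:1]), integer(8)))
}

# stable fingerprint of an R object (FNV-1a over its serialized bytes)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write / read a run configuration file
#'
#' YAML with two blocks: \code{arena} (the [arena_config()] fields) and
#' \code{ga} (the [ga_config()] fields) plus top-level \code{generations},
#' \code{fitness_mode} and \code{seed}.
#'
#' @param config An [arena_config()].
#' @param ga A [ga_config()].
#' @param path Output path.
#' @param generations,fitness_mode,seed Run parameters stored alongside.
#' @return \code{write_run_config}: the path, invisibly.
#' @export
write_run_config <- function(config, ga = ga_config(), path,
                             generations = 600,
                             fitness_mode = "collective", seed = 1) {
  x <- list(arena = lapply(unclass(config), function(v)
              if (is.matrix(v)) as.vector(t(v)) else v),
            ga = unclass(ga),
            generations = as.integer(generations),
            fitness_mode = fitness_mode,
            seed = as.integer(seed))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @return \code{read_run_config}: list with \code{config}, \code{ga},
#'   \code{generations}, \code{fitness_mode}, \code{seed}.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  a <- x$arena
  cfg <- arena_config(side_length = a$side_length,
                      zone_diameter = a$zone_diameter,
                      zone_centers = matrix(a$zone_centers, 2, 2, byrow = TRUE),
                      robot_diameter = a$robot_diameter,
                      steps_per_trial = a$steps_per_trial,
                      wheel_speed_max = a$wheel_speed_max,
                      collision_displacement = a$collision_displacement,
                      exclude_zones_at_init = a$exclude_zones_at_init)
  ga <- do.call(ga_config, x$ga)
  list(config = cfg, ga = ga, generations = x$generations,
       fitness_mode = x$fitness_mode, seed = x$seed)
}

#' Write a trial log as tabular text
#'
#' A JSON header line (prefixed \code{#}) records the seed, config hash and
#' pin/removal setting; the body is one CSV row per step with pose, wheel
#' commands, zone id, collision flag and (if logged) the 72 sensor values.
#'
#' @param log A \code{trial_log}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trial_log <- function(log, path) {
  steps <- nrow(log$control)
  header <- jsonlite::toJSON(list(seed = log$seed,
                                  config_hash = config_hash(log$config),
                                  pinned = log$pinned,
                                  removed = log$removed,
                                  sensors = !is.null(log$sensors)),
                             auto_unbox = TRUE, null = "null")
  body <- cbind(step = 1:steps, log$pose[-1, , drop = FALSE], log$control,
                log$zone, log$collided)
  if (!is.null(log$sensors)) body <- cbind(body, log$sensors)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  writeLines(paste0("#init,", paste(sprintf("%.17g", log$pose[1, ]),
                                    collapse = ",")), con)
  writeLines(paste(colnames(body), collapse = ","), con)
  writeLines(apply(body, 1, function(row)
    paste(sprintf("%.17g", row), collapse = ",")), con)
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path Input path.
#' @param config The [arena_config()] the log was produced under (logs store
#'   only its hash).
#' @return A \code{trial_log}.
#' @export
read_trial_log <- function(path, config) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  init <- as.numeric(strsplit(sub("^#init,", "", lines[2]), ",")[[1]])
  body <- utils::read.csv(text = lines[-(1:2)], check.names = FALSE)
  steps <- nrow(body)
  pose <- rbind(init, as.matrix(body[, 2:13]))
  rownames(pose) <- NULL
  sens <- if (isTRUE(header$sensors))
    as.matrix(body[, 29 + (1:72)]) else NULL
  zone <- as.matrix(body[, 22:25])
  storage.mode(zone) <- "integer"
  coll <- as.matrix(body[, 26:29])
  storage.mode(coll) <- "integer"
  new_trial_log(seed = header$seed, config = config,
                pinned = header$pinned,
                removed = if (length(header$removed)) header$removed else NULL,
                pose = pose, control = as.matrix(body[, 14:21]),
                zone = zone, collided = coll, sensors = sens)
}

#' Write / read a genotype archive
#'
#' Hex-text archive: a JSON manifest line (parameter ordering and map
#' version) followed by one TSV row per genotype
#' (\code{generation}, \code{population} colour, \code{index}, \code{hex}).
#'
#' @param rows Data frame with columns \code{generation},
#'   \code{population}, \code{index}, and a list/character column
#'   \code{genotype} of bit vectors or hex strings.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotype_archive <- function(rows, path) {
  manifest <- jsonlite::toJSON(list(
    map_version = GENOTYPE_MAP_VERSION,
    n_params = N_PARAMS, bits_per_param = BITS_PER_PARAM,
    weight_range = c(-5, 5),
    order = "input_hidden_row_major, hidden_bias, hidden_output_row_major, output_bias"),
    auto_unbox = TRUE)
  hex <- vapply(rows$genotype, function(g)
    if (is.character(g)) g else bits_to_hex(g), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", manifest), con)
  writeLines("generation\tpopulation\tindex\thex", con)
  writeLines(sprintf("%d\t%s\t%d\t%s", rows$generation, rows$population,
                     rows$index, hex), con)
  invisible(path)
}

#' @rdname write_genotype_archive
#' @return \code{read_genotype_archive}: data frame with columns
#'   \code{generation}, \code{population}, \code{index}, \code{genotype}
#'   (list of bit vectors), plus the manifest as an attribute.
#' @export
read_genotype_archive <- function(path) {
  lines <- readLines(path)
  manifest <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (!identical(as.character(manifest$map_version), GENOTYPE_MAP_VERSION))
    stop("genotype archive has unknown map version")
  tab <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE)
  tab$genotype <- lapply(tab$hex, hex_to_bits)
  tab$hex <- NULL
  attr(tab, "manifest") <- manifest
  tab
}

#' Save / load a replication to a directory of plain-text files
#'
#' Writes \code{config.yaml}, \code{group_fitness.csv},
#' \code{fitness.csv} (one row per genotype per generation),
#' \code{best_teams.txt} and \code{checkpoints.txt} (hex genotype
#' archives).
#'
#' @param replication A \code{replication_result}.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_replication <- function(replication, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(replication$config, replication$ga,
                   file.path(dir, "config.yaml"),
                   generations = replication$generations,
                   fitness_mode = replication$fitness_mode,
                   seed = replication$seed)
  utils::write.csv(data.frame(generation = seq_along(replication$group_fitness),
                              group_fitness = replication$group_fitness),
                   file.path(dir, "group_fitness.csv"), row.names = FALSE)
  size <- replication$ga$populations_size
  fit <- replication$fitness
  tab <- data.frame(
    generation = rep(seq_len(dim(fit)[1]), times = size * 4),
    population = rep(robot_colours(), each = dim(fit)[1] * size),
    index = rep(rep(seq_len(size), each = dim(fit)[1]), times = 4),
    fitness = as.vector(fit))
  utils::write.csv(tab, file.path(dir, "fitness.csv"), row.names = FALSE)
  bt <- do.call(rbind, lapply(seq_along(replication$best_teams), function(g)
    data.frame(generation = g, population = robot_colours(), index = 1L)))
  bt$genotype <- unlist(lapply(replication$best_teams, function(team)
    lapply(team, bits_to_hex)), recursive = FALSE)
  write_genotype_archive(bt, file.path(dir, "best_teams.txt"))
  cp <- list()
  for (g in names(replication$checkpoints)) {
    pops <- replication$checkpoints[[g]]
    for (p in 1:4) {
      cp[[length(cp) + 1]] <- data.frame(
        generation = as.integer(g), population = robot_colours()[p],
        index = seq_len(size))
      cp[[length(cp)]]$genotype <- lapply(pops[[p]]$genotypes, bits_to_hex)
    }
  }
  write_genotype_archive(do.call(rbind, cp), file.path(dir, "checkpoints.txt"))
  invisible(dir)
}

#' @rdname write_replication
#' @return \code{read_replication}: the reconstructed
#'   \code{replication_result}.
#' @export
read_replication <- function(dir) {
  rc <- read_run_config(file.path(dir, "config.yaml"))
  gf <- utils::read.csv(file.path(dir, "group_fitness.csv"))
  fit_tab <- utils::read.csv(file.path(dir, "fitness.csv"),
                             stringsAsFactors = FALSE)
  size <- rc$ga$populations_size
  gens <- max(fit_tab$generation)
  fit <- array(NA_real_, c(gens, size, 4))
  p_idx <- match(fit_tab$population, robot_colours())
  fit[cbind(fit_tab$generation, fit_tab$index, p_idx)] <- fit_tab$fitness
  bt_tab <- read_genotype_archive(file.path(dir, "best_teams.txt"))
  best_teams <- lapply(seq_len(gens), function(g) {
    rows <- bt_tab[bt_tab$generation == g, ]
    rows$genotype[match(robot_colours(), rows$population)]
  })
  cp_tab <- read_genotype_archive(file.path(dir, "checkpoints.txt"))
  checkpoints <- list()
  for (g in unique(cp_tab$generation)) {
    pops <- lapply(1:4, function(p) {
      rows <- cp_tab[cp_tab$generation == g &
                     cp_tab$population == robot_colours()[p], ]
      structure(list(genotypes = rows$genotype[order(rows$index)],
                     colour_role = robot_colours()[p]),
                class = "population")
    })
    checkpoints[[as.character(g)]] <- pops
  }
  last <- checkpoints[[as.character(max(cp_tab$generation))]]
  structure(list(group_fitness = gf$group_fitness, fitness = fit,
                 best_teams = best_teams, checkpoints = checkpoints,
                 populations = last, seed = rc$seed,
                 generations = as.integer(gens), ga = rc$ga,
                 fitness_mode = rc$fitness_mode, config = rc$config),
            class = "replication_result")
}
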