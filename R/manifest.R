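#' Example category/object specification table
#'
#' A synthetic six-category specification — three natural categories
#' (animals, plants, landscape elements) and three artificial ones
#' (vehicles, items, buildings), 18 object scenes each, 108 in total — with
#' placeholder prompts. The object names and prompt texts are illustrative
#' stand-ins, not a published stimulus list; supply your own table of the
#' same shape to plan a real stimulus set.
#'
#' @return data.frame with columns `category`, `kind`
#'   (`"natural"`/`"artificial"`), `object_id`, `prompt`.
#' @export
stimulus_category_table <- function() {
  objects <- list(
    animals = c("fish", "beaver", "fox", "owl", "horse", "elephant", "rabbit",
                "frog", "butterfly", "deer", "eagle", "turtle", "squirrel",
                "duck", "bear", "lion", "goat", "penguin"),
    plants = c("oak tree", "sunflower", "cactus", "fern", "rose bush",
               "bamboo", "maple tree", "mushroom", "water lily", "palm tree",
               "lavender", "pine tree", "ivy", "tulip", "birch tree", "moss",
               "orchid", "wheat"),
    `landscape elements` = c("mountain", "waterfall", "sand dune", "glacier",
                             "river bend", "cliff", "lake island", "volcano",
                             "canyon", "beach", "forest clearing",
                             "cave entrance", "hot spring", "meadow", "fjord",
                             "rock arch", "marsh", "snowfield"),
    vehicles = c("sailboat", "bicycle", "steam locomotive", "tractor",
                 "hot air balloon", "canoe", "motorcycle", "city bus",
                 "helicopter", "fire truck", "cargo ship", "glider",
                 "snowmobile", "taxi", "submarine", "tram", "camper van",
                 "rowboat"),
    items = c("chair", "teapot", "backpack", "umbrella", "wristwatch",
              "guitar", "lantern", "typewriter", "vase", "telescope",
              "sewing machine", "globe", "kettle", "armchair", "bookshelf",
              "camera", "clock", "basket"),
    buildings = c("lighthouse", "windmill", "observatory", "castle", "barn",
                  "greenhouse", "water tower", "cottage", "bridge", "pagoda",
                  "cathedral", "skyscraper", "watermill", "fort",
                  "train station", "stadium", "chapel", "farmhouse")
  )
  kinds <- c(animals = "natural", plants = "natural",
             `landscape elements` = "natural", vehicles = "artificial",
             items = "artificial", buildings = "artificial")
  do.call(rbind, lapply(names(objects), function(cat) {
    data.frame(
      category = cat, kind = kinds[[cat]],
      object_id = paste0(gsub(" ", "_", cat), "/", gsub(" ", "_", objects[[cat]])),
      prompt = sprintf(
        "high-detail photograph of a %s, centered in a coherent scene", objects[[cat]]),
      row.names = NULL
    )
  }))
}

#' Build a stimulus manifest from a category specification
#'
#' Expands a category/object table into the full generation plan: per object
#' scene, a list of exemplar seeds (one per exemplar image), the
#' interpolation grid (interior slerp positions) and file slots for the
#' exemplars, interpolations and final selected images. Image files are
#' referenced by the slots but never required to exist — the generation
#' adapter fills them.
#'
#' @param categories data.frame with columns `category`, `kind`,
#'   `object_id`, `prompt` (see [stimulus_category_table()]); must contain
#'   6 categories with 18 object scenes each.
#' @param base_seed integer from which all exemplar seeds are derived
#'   deterministically.
#' @param n_exemplars exemplar images per object scene (default 60).
#' @param n_interpolations interior interpolation steps (default 200).
#' @param n_selected images in the final continuum (default 10).
#' @return a `"stimulus_manifest"` list with `categories`, `scenes` (one
#'   entry per object scene) and the plan sizes.
#' @export
build_manifest <- function(categories = stimulus_category_table(),
                           base_seed = 1, n_exemplars = 60,
                           n_interpolations = 200, n_selected = 10) {
  needed <- c("category", "kind", "object_id", "prompt")
  missing <- setdiff(needed, colnames(categories))
  if (length(missing)) stop("category table missing columns: ",
                            paste(missing, collapse = ", "))
  cats <- unique(categories$category)
  if (length(cats) != 6L) {
    stop(sprintf("expected 6 categories, got %d", length(cats)))
  }
  per_cat <- table(categories$category)
  if (any(per_cat != 18L)) {
    stop("every category must contain exactly 18 object scenes; got counts: ",
         paste(sprintf("%s=%d", names(per_cat), per_cat), collapse = ", "))
  }
  if (anyDuplicated(categories$object_id)) stop("object ids must be unique")
  if (anyDuplicated(categories$prompt)) stop("prompts must be unique")
  if (any(!nzchar(categories$prompt))) stop("prompts must be non-empty")
  check_seed(base_seed)

  scenes <- lapply(seq_len(nrow(categories)), function(i) {
    row <- categories[i, ]
    oid <- row$object_id
    list(
      object_id = oid,
      category = row$category,
      kind = row$kind,
      prompt = row$prompt,
      exemplar_seeds = base_seed * 100000L + (i - 1L) * 1000L + seq_len(n_exemplars),
      interpolation_t = seq_len(n_interpolations) / (n_interpolations + 1),
      slots = list(
        exemplars = sprintf("%s/exemplar_%03d.png", oid, seq_len(n_exemplars)),
        interpolations = sprintf("%s/interp_%03d.png", oid, seq_len(n_interpolations)),
        selected = sprintf("%s/selected_%02d.png", oid, seq_len(n_selected))
      )
    )
  })
  names(scenes) <- categories$object_id
  structure(
    list(categories = categories, scenes = scenes,
         n_scenes = length(scenes), n_exemplars = n_exemplars,
         n_interpolations = n_interpolations, n_selected = n_selected,
         base_seed = base_seed),
    class = "stimulus_manifest"
  )
}

#' @export
print.stimulus_manifest <- function(x, ...) {
  cat(sprintf("Stimulus manifest: %d object scenes (%d categories), %d exemplars + %d interpolations -> %d selected per scene\n",
              x$n_scenes, length(unique(x$categories$category)),
              x$n_exemplars, x$n_interpolations, x$n_selected))
  invisible(x)
}

#' Validate a stimulus manifest
#'
#' Re-checks all structural invariants (scene count, plan sizes, unique ids
#' and prompts) and errors on the first violation, naming the offending
#' count or record.
#'
#' @param manifest a `"stimulus_manifest"`.
#' @export
validate_manifest <- function(manifest) {
  if (!inherits(manifest, "stimulus_manifest")) stop("not a stimulus manifest")
  if (manifest$n_scenes != 108L || length(manifest$scenes) != 108L) {
    stop(sprintf("manifest must contain 108 object scenes, found %d",
                 length(manifest$scenes)))
  }
  ids <- vapply(manifest$scenes, `[[`, "", "object_id")
  if (anyDuplicated(ids)) stop("duplicate object ids in manifest")
  prompts <- vapply(manifest$scenes, `[[`, "", "prompt")
  if (anyDuplicated(prompts)) stop("duplicate prompts in manifest")
  for (sc in manifest$scenes) {
    if (length(sc$exemplar_seeds) != manifest$n_exemplars) {
      stop(sprintf("scene %s: exemplar plan has %d seeds, expected %d",
                   sc$object_id, length(sc$exemplar_seeds), manifest$n_exemplars))
    }
    if (length(sc$interpolation_t) != manifest$n_interpolations) {
      stop(sprintf("scene %s: interpolation plan has %d steps, expected %d",
                   sc$object_id, length(sc$interpolation_t),
                   manifest$n_interpolations))
    }
  }
  invisible(TRUE)
}

#' Write/read a stimulus manifest as JSON
#' @param manifest a `"stimulus_manifest"`.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$categories <- as.data.frame(x$categories)
  x$scenes <- lapply(x$scenes, function(sc) {
    sc$exemplar_seeds <- as.integer(sc$exemplar_seeds)
    sc$interpolation_t <- as.numeric(sc$interpolation_t)
    sc
  })
  structure(x, class = "stimulus_manifest")
}

#' Pipeline run configuration
#'
#' Collects the knobs every stage reads: the master seed, continuum size,
#' SOE margin, t-STE alpha, CV folds, MCMC profile and distance backend.
#' All randomness in a run flows from `seed`.
#'
#' @param seed master integer seed.
#' @param k continuum candidates to select (default 9).
#' @param margin SOE hinge margin.
#' @param alpha t-STE kernel degrees of freedom.
#' @param folds CV folds.
#' @param mcmc `"test"` or `"full"` (see [mcmc_profile()]).
#' @param backend distance backend: `"euclidean"`, `"cosine"` or `"plugin"`.
#' @param paths named list of file paths, free-form.
#' @return a validated `"run_config"` list.
#' @export
run_config <- function(seed = 1, k = 9, margin = 0.1, alpha = 1, folds = 10,
                       mcmc = c("test", "full"),
                       backend = c("euclidean", "cosine", "plugin"),
                       paths = list()) {
  cfg <- list(seed = check_seed(seed) %||% 1L, k = as.integer(k),
              margin = margin, alpha = alpha, folds = as.integer(folds),
              mcmc = match.arg(mcmc), backend = match.arg(backend),
              paths = paths)
  assert_scalar_number(cfg$k, "k", lower = 1)
  assert_scalar_number(cfg$margin, "margin", lower = 0)
  assert_scalar_number(cfg$alpha, "alpha")
  if (cfg$alpha <= 0) stop("`alpha` must be > 0")
  assert_scalar_number(cfg$folds, "folds", lower = 2)
  structure(cfg, class = "run_config")
}

#' Structured run report (JSON lines)
#'
#' Validates stage outputs and emits one JSON record per stage capturing the
#' seed, parameters and row/element counts, plus a header record with the
#' configuration. Rerunning with the same inputs reproduces the report
#' byte-for-byte apart from the timestamp field.
#'
#' @param config a `"run_config"`.
#' @param stages named list; each element is a list with at least `ok`
#'   (logical) and `count` (number of rows/elements produced), plus any
#'   extra scalar metadata.
#' @param path optional file to write JSON lines to.
#' @param timestamp include a timestamp field (disable for byte-identical
#'   reports).
#' @return character vector of JSON lines, invisibly when `path` is given.
#' @export
run_report <- function(config, stages, path = NULL, timestamp = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(stages)) || any(!nzchar(names(stages)))) {
    stop("`stages` must be a fully named list")
  }
  header <- list(record = "config", seed = config$seed, k = config$k,
                 margin = config$margin, alpha = config$alpha,
                 folds = config$folds, mcmc = config$mcmc,
                 backend = config$backend)
  if (timestamp) header$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  ok_all <- TRUE
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (is.null(st$ok)) stop(sprintf("stage '%s' missing `ok` field", nm))
    ok_all <- ok_all && isTRUE(st$ok)
    rec <- c(list(record = "stage", stage = nm), st)
    lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }
  lines <- c(lines, jsonlite::toJSON(
    list(record = "summary", ok = ok_all, n_stages = length(stages)),
    auto_unbox = TRUE, digits = NA))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
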