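# Synthetic formulary generator.
#
# The generator states a simple world with the structure the downstream
# analyses assume: each formula belongs to one efficacy class; every class
# owns a small disjoint set of "main ingredient" plants used at elevated
# probability, all other plants are occasional supporting ingredients; each
# class owns a few class-specific pharmacological activities carried by its
# main plants, while a handful of general activities (antimicrobial-like) are
# carried by the main plants of every class.

#' Configuration for the synthetic formulary generator
#'
#' Defaults reproduce the scale of the canonical Jamu formulary: I = 3138
#' formulas over J = 465 plants, L = 9 efficacy classes with the published
#' class sizes (72, 249, 22, 980, 398, 840, 311, 107, 159 in the
#' \code{\link{jamu_classes}} order), and K = 46 pharmacological activities.
#' Structural parameters that the source data do not pin down scale with the
#' problem size: about 19\% of plants are main ingredients (split evenly
#' across classes), each class owns roughly \code{K/(2L)} specific activities,
#' and about \code{6K/46} activities are general.
#'
#' @param I,J,K,L numbers of formulas, plants, activities and efficacy classes.
#' @param class_proportions length-L simplex vector of class prevalences.
#'   Defaults to the published Jamu class sizes when L = 9, uniform otherwise.
#' @param class_names class codes; \code{\link{jamu_classes}} when L = 9.
#' @param n_main_per_class main-ingredient plants per class (disjoint sets).
#' @param p_main probability that a formula uses each main plant of its class.
#' @param p_support baseline usage probability for all other plants.
#' @param n_specific_activities_per_class,n_general_activities activity-group
#'   sizes; their total must not exceed K.
#' @param p_activity_noise probability of a spurious plant-activity link.
#' @param seed master seed; sub-streams for labels, usage and activities are
#'   derived from it so the three blocks are independently stable.
#' @return validated \code{jamu_config} list.
#' @export
jamu_config <- function(I = 3138, J = 465, K = 46, L = 9,
                        class_proportions = NULL,
                        class_names = NULL,
                        n_main_per_class = max(2L, round(0.19 * J / L)),
                        p_main = 0.6,
                        p_support = 0.02,
                        n_specific_activities_per_class = max(1L, round(K / (2 * L))),
                        n_general_activities = max(2L, round(6 * K / 46)),
                        p_activity_noise = 0.02,
                        seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- if (L == 9) {
      c(72, 249, 22, 980, 398, 840, 311, 107, 159) / 3138
    } else rep(1 / L, L)
  }
  if (is.null(class_names)) {
    class_names <- if (L == 9) jamu_classes() else paste0("C", seq_len(L))
  }
  cfg <- list(I = as.integer(I), J = as.integer(J), K = as.integer(K),
              L = as.integer(L),
              class_proportions = class_proportions,
              class_names = class_names,
              n_main_per_class = as.integer(n_main_per_class),
              p_main = p_main, p_support = p_support,
              n_specific_activities_per_class = as.integer(n_specific_activities_per_class),
              n_general_activities = as.integer(n_general_activities),
              p_activity_noise = p_activity_noise,
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(I >= 1, J >= 1, K >= 1, L >= 1)
    if (length(class_proportions) != L) {
      stop("class_proportions must have length L", call. = FALSE)
    }
    if (abs(sum(class_proportions) - 1) > 1e-12) {
      stop("class_proportions must sum to 1", call. = FALSE)
    }
    probs <- c(p_main, p_support, p_activity_noise, class_proportions)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
    if (n_main_per_class * L > J) {
      stop(sprintf("infeasible config: n_main_per_class * L = %d exceeds J = %d",
                   n_main_per_class * L, J), call. = FALSE)
    }
    if (n_specific_activities_per_class * L + n_general_activities > K) {
      stop("infeasible config: specific + general activities exceed K", call. = FALSE)
    }
    if (length(class_names) != L) stop("class_names must have length L", call. = FALSE)
  })
  structure(cfg, class = "jamu_config")
}

#' Simulate a synthetic formulary with known ground truth
#'
#' Formula classes are independent multinomial draws from
#' \code{class_proportions}.  Usage is Bernoulli: \code{p_main} for a
#' formula's own main plants, \code{p_support} elsewhere.  The activity
#' annotation links each class's main plants to that class's specific
#' activities and every main plant to the general activities, with spurious
#' links added at rate \code{p_activity_noise}.
#'
#' @param cfg a \code{\link{jamu_config}}.
#' @return list with \code{usage}, \code{labels}, \code{activity} and
#'   \code{truth} (main plants, specific activities and general activities by
#'   class), all reproducible from \code{cfg$seed}.
#' @export
simulate_formulary <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  # one derived stream per artifact so blocks do not perturb each other
  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)

  plant_ids    <- sprintf("P%03d", seq_len(cfg$J))
  activity_ids <- sprintf("A%02d", seq_len(cfg$K))
  formula_ids  <- sprintf("F%04d", seq_len(cfg$I))

  n_main <- cfg$n_main_per_class
  main_plants <- split(plant_ids[seq_len(n_main * cfg$L)],
                       rep(seq_len(cfg$L), each = n_main))
  names(main_plants) <- cfg$class_names
  n_spec <- cfg$n_specific_activities_per_class
  specific_acts <- split(activity_ids[seq_len(n_spec * cfg$L)],
                         rep(seq_len(cfg$L), each = n_spec))
  names(specific_acts) <- cfg$class_names
  general_acts <- activity_ids[n_spec * cfg$L + seq_len(cfg$n_general_activities)]

  set.seed(sub[1])
  labels <- sample(cfg$class_names, cfg$I, replace = TRUE,
                   prob = cfg$class_proportions)
  labels <- efficacy_labels(labels, cfg$class_names, formula_ids)

  set.seed(sub[2])
  P <- matrix(cfg$p_support, cfg$I, cfg$J, dimnames = list(formula_ids, plant_ids))
  for (cl in cfg$class_names) {
    rows <- which(labels == cl)
    P[rows, main_plants[[cl]]] <- cfg$p_main
  }
  X <- matrix(stats::rbinom(cfg$I * cfg$J, 1L, as.vector(P)), cfg$I, cfg$J,
              dimnames = dimnames(P))
  usage <- suppressMessages(usage_matrix(X, formula_ids, plant_ids))

  set.seed(sub[3])
  A <- matrix(stats::rbinom(cfg$J * cfg$K, 1L, cfg$p_activity_noise),
              cfg$J, cfg$K, dimnames = list(plant_ids, activity_ids))
  all_mains <- unlist(main_plants, use.names = FALSE)
  for (cl in cfg$class_names) {
    A[main_plants[[cl]], specific_acts[[cl]]] <- 1
  }
  A[all_mains, general_acts] <- 1
  activity <- activity_matrix(A, plant_ids, activity_ids)

  list(usage = usage, labels = labels, activity = activity,
       truth = list(main_plants = main_plants,
                    specific_activities = specific_acts,
                    general_activities = general_acts),
       config = cfg)
}
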