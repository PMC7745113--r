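# Default configuration for the flowreactor pipeline.
#
# Units are stated per key.  Kinetic parameters come from an Arrhenius fit of
# isothermal batch monitoring of the M4MAA + DMF-DMA enamine condensation.
# Species property values marked "representative" are literature-typical
# magnitudes for these neat organic liquids, shipped as documented,
# overridable defaults; no acceptance-level result depends on their exact
# values (the reaction is kinetically limited).
species:
  M4MAA:            # methyl 4-methoxyacetoacetate, reactant (limiting at chi > 1)
    role: reactant_a
    density: 1118.0                # kg m-3
    viscosity: 3.0e-3              # Pa s, representative
    molar_heat_capacity: 250.0     # J mol-1 K-1, representative
    molar_mass: 0.14614            # kg mol-1
  DMF_DMA:          # N,N-dimethylformamide dimethyl acetal, reactant (limiting at chi < 1)
    role: reactant_b
    density: 897.0                 # kg m-3
    viscosity: 0.65e-3             # Pa s, representative
    molar_heat_capacity: 220.0     # J mol-1 K-1, representative
    molar_mass: 0.11916            # kg mol-1
  Enamine:          # condensation product, the yield response species
    role: product
    density: 1150.0                # kg m-3, representative
    viscosity: 5.0e-3              # Pa s, representative
    molar_heat_capacity: 330.0     # J mol-1 K-1, representative
    molar_mass: 0.20122            # kg mol-1
  MeOH:             # methanol condensation byproduct (2 mol per mol product)
    role: byproduct
    density: 792.0                 # kg m-3
    viscosity: 0.54e-3             # Pa s
    molar_heat_capacity: 81.1      # J mol-1 K-1
    molar_mass: 0.03204            # kg mol-1
  Impurity:         # unidentified product-consuming impurity (synthetic stand-in)
    role: impurity
    density: 1150.0                # kg m-3, copy of product (structure unknown)
    viscosity: 5.0e-3              # Pa s
    molar_heat_capacity: 330.0     # J mol-1 K-1
    molar_mass: 0.20122            # kg mol-1

kinetics:
  pre_exponential: 2.0e+8          # L mol-1 min-1 (second order, first order in each reactant)
  activation_energy: 57930.0       # J mol-1
  gas_constant: 8.314              # J mol-1 K-1
  heat_of_reaction: -50000.0       # J mol-1.  PLACEHOLDER: exothermic, plausible
                                   # magnitude; measured value not published.
                                   # Only the energy balance uses it.
  byproduct_stoichiometry: 2       # mol MeOH per mol Enamine

# Two-level factor ranges of the screening design (A..E order fixed).
factors:
  length:         {low: 1.0,  high: 5.0}    # m
  inner_diameter: {low: 0.25, high: 1.0}    # mm
  flow_rate:      {low: 0.1,  high: 1.0}    # mL min-1 (total of both feeds)
  temperature:    {low: 10.0, high: 40.0}   # degC bath temperature
  molar_ratio:    {low: 0.95, high: 1.5}    # DMF-DMA : M4MAA feed mole ratio

grid:
  n_radial: 32                     # radial finite-volume cells
  n_axial: 400                     # axial cells
  diffusivity: 1.0e-9              # m2 s-1, isotropic species diffusion coefficient
  thermal_conductivity: 0.15       # W m-1 K-1, organic-liquid scale
  energy_equation: true            # false -> isothermal at bath temperature
  inlet_temperature: 295.15        # K, room-temperature feeds
  end_time_multiple: 5.0           # integrate to this many residence times
  steady_tolerance: 0.01           # relative yield tolerance for steady-state detection
  cfl: 0.9                         # advective Courant number of the axial sweep
  n_save: 200                      # saved outlet-yield time points

synthetic_experiment:
  # Pseudo-experimental campaign generator.  All parameters are synthetic
  # stand-ins: the real impurity kinetics and assay noise are unknown.
  impurity_pre_exponential: 1.0e+9    # s-1, first-order consumption of Enamine
  impurity_activation_energy: 80000.0 # J mol-1 (steeper than the main reaction,
                                      # so the channel matters only when hot)
  bath_bias: -0.5                     # K, constant offset of the water bath
  bath_gradient_fraction: 0.01        # fraction of the bath-ambient difference
                                      # lost to gradients along the coil
  ambient_temperature: 295.15         # K, lab ambient used by the gradient term
  replicate_noise_cv: 0.03            # lognormal coefficient of variation
  replicates: 3
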