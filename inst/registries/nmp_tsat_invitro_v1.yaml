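name: nmp_tsat_invitro
version: '1.0'
study_system: in_vitro
criteria:
- id: pc_size
  label: Particle size and size distribution
  category: particle_characterization
  red: yes
  score_guidance:
    '0': Particle size not reported or ambiguous
    '1': Nominal or supplier-reported size only, or measured outside the exposure
      medium
    '2': Size distribution measured by the authors in the exposure medium (e.g. DLS,
      microscopy) with dispersion statistics
- id: pc_shape
  label: Particle shape (sphere, fragment, fibre)
  category: particle_characterization
  red: yes
  score_guidance:
    '0': Shape not reported
    '1': Shape stated from supplier information without confirmation
    '2': Shape confirmed by imaging; for fibres, aspect ratio, length-to-diameter
      relationship and rigidity are addressed
  applicability_note: Fibre-specific sub-aspects (aspect ratio, flexural rigidity,
    biopersistence) are folded into this criterion
- id: pc_polymer
  label: Polymer type verification
  category: particle_characterization
  red: yes
  score_guidance:
    '0': Polymer type not reported
    '1': Polymer type taken from supplier information only
    '2': Polymer composition verified analytically (e.g. FTIR, Raman)
- id: pc_source
  label: Source of the particles
  category: particle_characterization
  red: yes
  score_guidance:
    '0': Particle source not reported
    '1': Supplier named without production details
    '2': Source and production process of the particles described
- id: pc_surface_chemistry
  label: Surface chemistry and charge
  category: particle_characterization
  red: no
  score_guidance:
    '0': Surface chemistry not reported
    '1': Nominal surface properties from supplier data only
    '2': Surface charge or chemistry measured in the exposure medium (e.g. zeta potential,
      functional groups)
- id: pc_chemical_purity
  label: Chemical purity of the test material
  category: particle_characterization
  red: no
  score_guidance:
    '0': Chemical purity not addressed
    '1': Purity addressed only qualitatively (e.g. a stated grade)
    '2': Residual monomers, additives, surfactants or dispersants quantified
- id: pc_microbial_contamination
  label: Microbial contamination / endotoxin testing
  category: particle_characterization
  red: no
  score_guidance:
    '0': Microbial contamination not addressed
    '1': Sterile handling described without contamination testing
    '2': Endotoxin or other microbial contamination of the test material tested and
      reported
- id: pc_production_cleaning
  label: Particle production and cleaning procedures
  category: particle_characterization
  red: no
  score_guidance:
    '0': No information on production or cleaning
    '1': Production or cleaning only partially described
    '2': Production method and any cleaning of the particles described
- id: sd_cell_model_source
  label: Cell model and its source
  category: study_design
  red: no
  score_guidance:
    '0': Cell model not adequately identified
    '1': Cell model named without sourcing detail
    '2': Cell model, origin and authentication reported
- id: sd_culture_conditions
  label: Culture and maintenance conditions
  category: study_design
  red: no
  score_guidance:
    '0': Culture conditions not reported
    '1': Culture conditions partially reported
    '2': Culture conditions reported (medium, passage, submerged vs air-liquid interface)
- id: sd_replicates
  label: Independent replicates per exposure dose
  category: study_design
  red: no
  score_guidance:
    '0': Replication not reported
    '1': Replication unclear or technical replicates only
    '2': Number of independent replicates per dose reported and adequate
- id: sd_administration_route
  label: Administration route
  category: study_design
  red: no
  score_guidance:
    '0': Administration route unclear
    '1': Route stated without procedural detail
    '2': Administration route fully described and appropriate for the exposure pathway
- id: sd_vehicle_medium
  label: Vehicle / exposure medium
  category: study_design
  red: no
  score_guidance:
    '0': Vehicle or medium not reported
    '1': Vehicle or medium named without composition
    '2': Composition of the vehicle or exposure medium reported, with a vehicle control
- id: sd_dose_metric
  label: Dose metric reporting
  category: study_design
  red: no
  score_guidance:
    '0': Dose metric unclear or not reported
    '1': A single dose metric reported
    '2': Concentrations reported in more than one dose metric (e.g. mass plus particle
      count or surface area)
- id: sd_homogeneity
  label: Homogeneity of particles in the culture medium
  category: study_design
  red: no
  score_guidance:
    '0': Homogeneity not addressed
    '1': Dispersion procedures (e.g. sonication, stirring) described without verification
    '2': Homogeneity of the particle suspension verified analytically
- id: sd_stability
  label: Particle stability in the culture medium
  category: study_design
  red: no
  score_guidance:
    '0': Stability not addressed
    '1': Stability addressed qualitatively
    '2': Stability / agglomeration state measured over the exposure period
- id: sd_frequency_duration
  label: Frequency and duration of exposure
  category: study_design
  red: no
  score_guidance:
    '0': Frequency and duration not reported
    '1': Frequency or duration partially reported
    '2': Frequency and duration of exposure fully reported
- id: sd_negative_control
  label: Negative / vehicle control
  category: study_design
  red: no
  score_guidance:
    '0': No negative control
    '1': Control mentioned but results unclear
    '2': Negative or vehicle control included and its results reported
- id: sd_positive_control
  label: Positive or benchmark particle control
  category: study_design
  red: no
  score_guidance:
    '0': No positive control
    '1': Historical or literature control referenced only
    '2': Positive control or benchmark particle included to demonstrate test-system
      performance
- id: ra_endpoints
  label: Endpoints reported and their relevance
  category: risk_assessment
  red: yes
  score_guidance:
    '0': Endpoints unclear or not interpretable
    '1': Sub-organismal biomarker endpoints only
    '2': Endpoints clearly defined and include organism-level effects or a link to
      an adverse outcome
- id: ra_dose_response
  label: Dose-response design
  category: risk_assessment
  red: yes
  score_guidance:
    '0': A single concentration, or no control
    '1': Two concentration doses plus a control
    '2': At least three concentration doses plus a control, spanning a concentration
      range of 3x or more
- id: ra_statistics
  label: Statistical methods
  category: risk_assessment
  red: no
  score_guidance:
    '0': No statistical analysis reported
    '1': Methods stated without sufficient detail
    '2': Statistical methods stated, appropriate and reported with error estimates
- id: ra_environmental_relevance
  label: Environmental relevance of particles and concentrations
  category: risk_assessment
  red: no
  score_guidance:
    '0': No consideration of environmental relevance
    '1': Relevance partially addressed
    '2': Particle types and concentrations environmentally relevant or their choice
      justified
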