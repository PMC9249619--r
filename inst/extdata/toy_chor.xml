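<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="toy_chor_v1" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_glc_e" name="glucose" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_glc_c" name="glucose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_chor_c" name="chorismate-like hub" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_trp_c" name="tryptophan-like" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_phe_c" name="phenylalanine-like" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_ent_c" name="enterochelin-like" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_paf_e" name="product" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="fb_1" value="-10" constant="true"/>
      <parameter id="fb_2" value="0" constant="true"/>
      <parameter id="fb_3" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_aroT" fbc:label="aroT"/>
      <fbc:geneProduct fbc:id="G_entA" fbc:label="entA"/>
      <fbc:geneProduct fbc:id="G_papA" fbc:label="papA"/>
      <fbc:geneProduct fbc:id="G_pheA" fbc:label="pheA"/>
      <fbc:geneProduct fbc:id="G_trpA1" fbc:label="trpA1"/>
      <fbc:geneProduct fbc:id="G_trpA2" fbc:label="trpA2"/>
      <fbc:geneProduct fbc:id="G_tyrA" fbc:label="tyrA"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_glc" name="glucose exchange" reversible="true" fast="false" fbc:lowerFluxBound="fb_1" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_T_glc" name="glucose transport" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_R_chor" name="hub supply" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_glc_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_chor_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_aroT"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R_trp" name="trp branch" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_chor_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_trp_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_trpA1"/>
            <fbc:geneProductRef fbc:geneProduct="G_trpA2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_DM_trp" name="trp demand" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_trp_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_R_phe" name="phe branch" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_chor_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_phe_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_pheA"/>
            <fbc:geneProductRef fbc:geneProduct="G_tyrA"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_DM_phe" name="phe demand" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_phe_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_R_ent" name="ent overflow branch" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_chor_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_ent_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_entA"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_DM_ent" name="ent demand" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_ent_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_BIOMASS" name="biomass" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_trp_c" stoichiometry="1" constant="true"/>
          <speciesReference species="M_phe_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_R_pap" name="product branch" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_chor_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_paf_e" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_papA"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_EX_paf" name="product exchange" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_paf_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
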