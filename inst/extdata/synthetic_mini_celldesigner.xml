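<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4"
      xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner"
      level="2" version="4">
  <model id="synthetic_mini" name="synthetic mini clock module">
    <annotation>
      <celldesigner:extension>
        <celldesigner:listOfIncludedSpecies>
          <celldesigner:species id="is1" name="ARNTL" complexSpecies="s3">
            <celldesigner:annotation>
              <celldesigner:speciesIdentity>
                <celldesigner:class>PROTEIN</celldesigner:class>
                <celldesigner:proteinReference>pr1</celldesigner:proteinReference>
                <celldesigner:state>
                  <celldesigner:listOfModifications>
                    <celldesigner:modification residue="rs1" state="phosphorylated"/>
                  </celldesigner:listOfModifications>
                </celldesigner:state>
              </celldesigner:speciesIdentity>
            </celldesigner:annotation>
          </celldesigner:species>
          <celldesigner:species id="is2" name="CLOCK" complexSpecies="s3">
            <celldesigner:annotation>
              <celldesigner:speciesIdentity>
                <celldesigner:class>PROTEIN</celldesigner:class>
                <celldesigner:proteinReference>pr2</celldesigner:proteinReference>
              </celldesigner:speciesIdentity>
            </celldesigner:annotation>
          </celldesigner:species>
        </celldesigner:listOfIncludedSpecies>
        <celldesigner:listOfProteins>
          <celldesigner:protein id="pr1" name="ARNTL" type="GENERIC">
            <celldesigner:listOfModificationResidues>
              <celldesigner:modificationResidue id="rs1" name="S90"/>
            </celldesigner:listOfModificationResidues>
          </celldesigner:protein>
          <celldesigner:protein id="pr2" name="CLOCK" type="GENERIC"/>
        </celldesigner:listOfProteins>
      </celldesigner:extension>
    </annotation>
    <listOfCompartments>
      <compartment id="c1" name="Cytoplasm"/>
      <compartment id="c2" name="Nucleoplasm"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="s1" name="ARNTL" compartment="c1">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
              <celldesigner:proteinReference>pr1</celldesigner:proteinReference>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
                   xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#s1">
              <bqbiol:is>
                <rdf:Bag>
                  <rdf:li rdf:resource="http://identifiers.org/uniprot/Q9WTL8"/>
                </rdf:Bag>
              </bqbiol:is>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="s2" name="CLOCK" compartment="c2">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
              <celldesigner:proteinReference>pr2</celldesigner:proteinReference>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="s3" name="ARNTL:CLOCK" compartment="c2">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>COMPLEX</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="s4" name="NAD" compartment="c2">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>SIMPLE_MOLECULE</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="s5" name="SIRT1" compartment="c2">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1">
        <annotation>
          <celldesigner:extension>
            <celldesigner:reactionType>HETERODIMER_ASSOCIATION</celldesigner:reactionType>
          </celldesigner:extension>
        </annotation>
        <listOfReactants>
          <speciesReference species="s1"/>
          <speciesReference species="s2"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="s3"/>
        </listOfProducts>
      </reaction>
      <reaction id="r2">
        <annotation>
          <celldesigner:extension>
            <celldesigner:reactionType>STATE_TRANSITION</celldesigner:reactionType>
            <celldesigner:listOfModification>
              <celldesigner:modification modifiers="s4" type="CATALYSIS"/>
            </celldesigner:listOfModification>
          </celldesigner:extension>
        </annotation>
        <listOfReactants>
          <speciesReference species="s3"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="s5"/>
        </listOfProducts>
        <listOfModifiers>
          <modifierSpeciesReference species="s4"/>
        </listOfModifiers>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
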