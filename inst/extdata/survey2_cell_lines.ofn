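Prefix(:=<http://www.ebi.ac.uk/efo/example#>)
Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)
Ontology(<http://www.ebi.ac.uk/efo/example>
Declaration(Class(:HeLa))
Declaration(Class(:4470))
Declaration(Class(:AraCResistantMurineLeukemia))
Declaration(Class(:B117H))
Declaration(Class(:B140H))
Declaration(Class(:genetic_disorder))
Declaration(Class(:cell_line))
Declaration(Class(:cervical_carcinoma))
Declaration(Class(:HomoSapiens))
Declaration(Class(:epithelial_cell))
Declaration(Class(:cervix))
Declaration(Class(:MusMusculus))
Declaration(Class(:bone_marrow))
Declaration(Class(:disease))
Declaration(Class(:normal))
Declaration(Class(:uninfected))
Declaration(ObjectProperty(:bearer_of))
Declaration(ObjectProperty(:derives_from))
AnnotationAssertion(rdfs:label :HeLa "HeLa")
AnnotationAssertion(rdfs:label :4470 "4470")
AnnotationAssertion(rdfs:label :AraCResistantMurineLeukemia "Ara-C-resistant murine leukemia")
AnnotationAssertion(rdfs:label :B117H "B117H")
AnnotationAssertion(rdfs:label :B140H "B140H")
AnnotationAssertion(rdfs:label :genetic_disorder "genetic disorder")
AnnotationAssertion(rdfs:label :cell_line "cell line")
AnnotationAssertion(rdfs:label :cervical_carcinoma "cervical carcinoma")
AnnotationAssertion(rdfs:label :HomoSapiens "Homo sapiens")
AnnotationAssertion(rdfs:label :epithelial_cell "epithelial cell")
AnnotationAssertion(rdfs:label :cervix "cervix")
AnnotationAssertion(rdfs:label :MusMusculus "Mus musculus")
AnnotationAssertion(rdfs:label :bone_marrow "bone marrow")
AnnotationAssertion(rdfs:label :disease "disease")
AnnotationAssertion(rdfs:label :normal "normal")
AnnotationAssertion(rdfs:label :uninfected "uninfected")
SubClassOf(:HeLa ObjectSomeValuesFrom(:bearer_of :cervical_carcinoma))
SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :HomoSapiens))
SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :epithelial_cell))
SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :cervix))
SubClassOf(:HeLa :cell_line)
SubClassOf(:4470 ObjectSomeValuesFrom(:derives_from :MusMusculus))
SubClassOf(:4470 ObjectSomeValuesFrom(:derives_from :bone_marrow))
SubClassOf(:4470 :cell_line)
SubClassOf(:AraCResistantMurineLeukemia :cell_line)
SubClassOf(:B117H :AraCResistantMurineLeukemia)
SubClassOf(:B140H :AraCResistantMurineLeukemia)
SubClassOf(:AraCResistantMurineLeukemia ObjectSomeValuesFrom(:derives_from :MusMusculus))
SubClassOf(:genetic_disorder :disease)
DisjointClasses(:genetic_disorder :normal)
DisjointClasses(:genetic_disorder :uninfected)
)
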