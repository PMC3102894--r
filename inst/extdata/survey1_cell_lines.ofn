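Prefix(:=<http://www.ebi.ac.uk/efo/example#>)
Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)
Ontology(<http://www.ebi.ac.uk/efo/example>
Declaration(Class(:22rv1))
Declaration(Class(:HeLa))
Declaration(Class(:GM18507))
Declaration(Class(:BDCM))
Declaration(Class(:cell_line))
Declaration(Class(:prostate_carcinoma))
Declaration(Class(:cervical_carcinoma))
Declaration(Class(:HomoSapiens))
Declaration(Class(:prostate))
Declaration(Class(:epithelial_cell))
Declaration(Class(:cervix))
Declaration(Class(:male))
Declaration(Class(:lymphoblast))
Declaration(ObjectProperty(:bearer_of))
Declaration(ObjectProperty(:derives_from))
Declaration(ObjectProperty(:has_quality))
AnnotationAssertion(rdfs:label :22rv1 "22rv1")
AnnotationAssertion(rdfs:label :HeLa "HeLa")
AnnotationAssertion(rdfs:label :GM18507 "GM18507")
AnnotationAssertion(rdfs:label :BDCM "BDCM")
AnnotationAssertion(rdfs:label :cell_line "cell line")
AnnotationAssertion(rdfs:label :prostate_carcinoma "prostate carcinoma")
AnnotationAssertion(rdfs:label :cervical_carcinoma "cervical carcinoma")
AnnotationAssertion(rdfs:label :HomoSapiens "Homo sapiens")
AnnotationAssertion(rdfs:label :prostate "prostate")
AnnotationAssertion(rdfs:label :epithelial_cell "epithelial cell")
AnnotationAssertion(rdfs:label :cervix "cervix")
AnnotationAssertion(rdfs:label :male "male")
AnnotationAssertion(rdfs:label :lymphoblast "lymphoblast")
SubClassOf(:22rv1 :cell_line)
SubClassOf(:22rv1 ObjectSomeValuesFrom(:bearer_of :prostate_carcinoma))
SubClassOf(:22rv1 ObjectSomeValuesFrom(:derives_from :HomoSapiens))
SubClassOf(:22rv1 ObjectSomeValuesFrom(:derives_from :prostate))
SubClassOf(:HeLa :cell_line)
SubClassOf(:HeLa ObjectSomeValuesFrom(:bearer_of :cervical_carcinoma))
SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :HomoSapiens))
SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :epithelial_cell))
SubClassOf(:HeLa ObjectSomeValuesFrom(:derives_from :cervix))
SubClassOf(:GM18507 :cell_line)
SubClassOf(:GM18507 ObjectSomeValuesFrom(:has_quality :male))
SubClassOf(:GM18507 ObjectSomeValuesFrom(:derives_from :HomoSapiens))
SubClassOf(:GM18507 ObjectSomeValuesFrom(:derives_from :lymphoblast))
SubClassOf(:BDCM :cell_line)
)
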