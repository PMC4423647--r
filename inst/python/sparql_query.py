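#!/usr/bin/env python
"""SPARQL evaluation helper.

Loads RDF data files into an in-process rdflib graph and either runs a
SPARQL query (results as SPARQL-results JSON on stdout) or re-serializes
the data as canonical sorted N-Triples. Exit codes distinguish failure
classes so the caller can report them precisely:

  0  success
  2  query syntax error
  3  data file unreadable/unparseable
  4  remote SERVICE failure during federated execution
  5  other evaluation error
"""

import argparse
import sys


def guess_format(path):
    lower = path.lower()
    if lower.endswith((".nt", ".ntriples")):
        return "nt"
    if lower.endswith((".ttl", ".turtle")):
        return "turtle"
    if lower.endswith((".rdf", ".xml", ".owl")):
        return "xml"
    return "turtle"


def main():
    parser = argparse.ArgumentParser()
    parser.add_argument("mode", choices=["query", "to_nt"])
    parser.add_argument("--data", action="append", default=[])
    parser.add_argument("--query")
    args = parser.parse_args()

    import rdflib

    graph = rdflib.Graph()
    for path in args.data:
        try:
            graph.parse(path, format=guess_format(path))
        except Exception as exc:  # noqa: BLE001
            sys.stderr.write("cannot load data file %s: %s\n" % (path, exc))
            sys.exit(3)

    if args.mode == "to_nt":
        def term_nt(t):
            # keep literal lexical forms verbatim (Literal.n3() would
            # normalize e.g. xsd:double values)
            if isinstance(t, rdflib.Literal):
                esc = (
                    str(t)
                    .replace("\\", "\\\\")
                    .replace('"', '\\"')
                    .replace("\n", "\\n")
                    .replace("\r", "\\r")
                    .replace("\t", "\\t")
                )
                if t.datatype is not None:
                    return '"%s"^^<%s>' % (esc, t.datatype)
                if t.language:
                    return '"%s"@%s' % (esc, t.language)
                return '"%s"' % esc
            if isinstance(t, rdflib.URIRef):
                return "<%s>" % t
            return t.n3()

        lines = sorted(
            "%s %s %s ." % (term_nt(s), term_nt(p), term_nt(o))
            for s, p, o in graph
        )
        sys.stdout.write("\n".join(lines) + ("\n" if lines else ""))
        return

    try:
        with open(args.query, encoding="utf-8") as handle:
            query_text = handle.read()
    except OSError as exc:
        sys.stderr.write("cannot read query file: %s\n" % exc)
        sys.exit(3)

    from pyparsing.exceptions import ParseException
    from rdflib.plugins.sparql import prepareQuery

    try:
        prepared = prepareQuery(query_text)
    except ParseException as exc:
        sys.stderr.write(
            "SPARQL syntax error at line %d column %d: %s\n"
            % (exc.lineno, exc.col, exc.msg)
        )
        sys.exit(2)
    except Exception as exc:  # noqa: BLE001
        sys.stderr.write("SPARQL syntax error: %s\n" % exc)
        sys.exit(2)

    try:
        result = graph.query(prepared)
        payload = result.serialize(format="json")
    except Exception as exc:  # noqa: BLE001
        name = type(exc).__name__
        if any(key in name for key in ("URL", "HTTP", "Connection", "Timeout")):
            sys.stderr.write("remote SERVICE failure: %s\n" % exc)
            sys.exit(4)
        sys.stderr.write("query evaluation error: %s\n" % exc)
        sys.exit(5)

    sys.stdout.buffer.write(payload)


if __name__ == "__main__":
    main()
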